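#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Brute-force reference scorer for semi-global affine-gap alignment.
// Recursively enumerates every monotone alignment path (no DP tables, no
// memoisation) and returns the best score.  Exponential: intended for the
// validation suite on sequences of length <= ~10 only; the production
// aligner (align_sg_cpp) is checked against this on small cases.

namespace {

struct Enum {
  const std::string& q;
  const std::string& r;
  int match, mismatch, go, ge;  // go = open+extend cost of a 1-base gap
  int best;

  Enum(const std::string& q_, const std::string& r_,
       int ma, int mi, int open, int ext)
      : q(q_), r(r_), match(ma), mismatch(mi),
        go(open + ext), ge(ext), best(INT_MIN / 4) {}

  // state: 0 = last op aligned/none, 1 = inside insertion, 2 = inside deletion
  void rec(size_t i, size_t j, int state, int score) {
    if (i == q.size()) {            // trailing reference bases are free
      if (score > best) best = score;
      return;
    }
    if (j < r.size()) {
      const int s = (q[i] == r[j] && q[i] != 'N') ? match : -mismatch;
      rec(i + 1, j + 1, 0, score + s);
      rec(i, j + 1, 2, score - (state == 2 ? ge : go));
    }
    rec(i + 1, j, 1, score - (state == 1 ? ge : go));
  }
};

}  // namespace

// [[Rcpp::export]]
int align_score_enum_cpp(const std::string& query, const std::string& ref,
                         int match, int mismatch, int gap_open,
                         int gap_extend) {
  if (query.size() > 10 || ref.size() > 10)
    stop("enumeration oracle is limited to sequences of length <= 10");
  Enum e(query, ref, match, mismatch, gap_open, gap_extend);
  // free leading reference skip: enumerate every start offset
  for (size_t j0 = 0; j0 <= ref.size(); ++j0) e.rec(0, j0, 0, 0);
  return e.best;
}
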