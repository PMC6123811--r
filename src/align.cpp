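#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global ("fitting") alignment of a full query inside a reference with
// affine gap costs (Gotoh).  End gaps on the *reference* are free: the query
// may start and end anywhere on the reference, but every query base is
// aligned or inserted.  A gap of length L costs gap_open + L * gap_extend.
//
// Tie-breaking (deterministic):
//   * in H cells, diagonal (match/mismatch) beats deletion beats insertion;
//   * gap states prefer closing the gap (coming from H) on ties;
//   * among equal-scoring alignment end points the smallest reference end is
//     chosen, which for repeated exact placements yields the leftmost start.
//
// 'N' (either side) always scores as a mismatch.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export]]
List align_sg_cpp(const std::string& query, const std::string& ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)query.size();
  const int n = (int)ref.size();
  const int go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const int ge = gap_extend;

  std::vector<int> H((size_t)(m + 1) * (n + 1));
  std::vector<int> E((size_t)(m + 1) * (n + 1));  // gap in ref (insertion)
  std::vector<int> F((size_t)(m + 1) * (n + 1));  // gap in query (deletion)
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) {   // free leading reference skip
    H[at(0, j)] = 0;
    E[at(0, j)] = NEG_INF;
    F[at(0, j)] = NEG_INF;
  }
  for (int i = 1; i <= m; ++i) {
    E[at(i, 0)] = std::max(H[at(i - 1, 0)] - go, E[at(i - 1, 0)] - ge);
    F[at(i, 0)] = NEG_INF;
    H[at(i, 0)] = E[at(i, 0)];
    const char qc = query[i - 1];
    const size_t row = at(i, 0), prow = at(i - 1, 0);
    for (int j = 1; j <= n; ++j) {
      const int e = std::max(H[prow + j] - go, E[prow + j] - ge);
      const int f = std::max(H[row + j - 1] - go, F[row + j - 1] - ge);
      const char rc = ref[j - 1];
      const int s = (qc == rc && qc != 'N') ? match : -mismatch;
      int h = H[prow + j - 1] + s;
      if (f > h) h = f;
      if (e > h) h = e;
      E[row + j] = e;
      F[row + j] = f;
      H[row + j] = h;
    }
  }

  int best = NEG_INF, jend = 0;
  for (int j = 0; j <= n; ++j)
    if (H[at(m, j)] > best) { best = H[at(m, j)]; jend = j; }

  // traceback
  std::vector<char> ops;
  int i = m, j = jend, state = 0;  // 0=H, 1=E(ins), 2=F(del)
  while (i > 0) {
    if (state == 0) {
      const char qc = query[i - 1];
      if (j > 0) {
        const char rc = ref[j - 1];
        const int s = (qc == rc && qc != 'N') ? match : -mismatch;
        if (H[at(i, j)] == H[at(i - 1, j - 1)] + s) {
          ops.push_back('M'); --i; --j; continue;
        }
        if (H[at(i, j)] == F[at(i, j)]) { state = 2; continue; }
      }
      state = 1;  // must be insertion
    } else if (state == 1) {
      ops.push_back('I');
      if (H[at(i - 1, j)] - go == E[at(i, j)]) state = 0;
      --i;
    } else {
      ops.push_back('D');
      if (H[at(i, j - 1)] - go == F[at(i, j)]) state = 0;
      --j;
    }
  }
  const int ref_start = j;

  // run-length encode (ops are reversed)
  std::vector<char> run_op;
  std::vector<int> run_len;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    if (!run_op.empty() && run_op.back() == ops[k]) {
      ++run_len.back();
    } else {
      run_op.push_back(ops[k]);
      run_len.push_back(1);
    }
  }
  CharacterVector rops(run_op.size());
  for (size_t k = 0; k < run_op.size(); ++k) rops[k] = std::string(1, run_op[k]);

  return List::create(_["score"] = best,
                      _["ops"] = rops,
                      _["lengths"] = IntegerVector(run_len.begin(), run_len.end()),
                      _["ref_start"] = ref_start,
                      _["ref_end"] = jend);
}
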