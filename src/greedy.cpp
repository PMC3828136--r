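#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stochastic greedy strain minimization over residue labellings.
//
// Moves a random residue to a random other domain and accepts iff the
// total intra-domain strain strictly decreases (ties rejected) and the
// source domain is not emptied.  Stops once `stall` consecutive
// proposals have been rejected, then (optionally) runs deterministic
// best-move sweeps until one-move local optimality.  Uses R's RNG, so
// results are reproducible from set.seed().

static double move_delta(const double* S, const int* lab, int n,
                         int i, int a, int d) {
  // strain change of relabelling residue i from domain a to d
  double snew = 0.0, sold = 0.0;
  const double* col = S + (size_t)i * n;  // column i (S symmetric)
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const int lj = lab[j];
    if (lj == d) snew += col[j];
    else if (lj == a) sold += col[j];
  }
  return snew - sold;
}

// [[Rcpp::export(name = ".greedy_cpp")]]
List greedy_cpp(NumericMatrix S, IntegerVector labels0, int Q,
                int stall, bool polish, bool record_trace) {
  const int n = S.nrow();
  const double* Sp = REAL(S);
  std::vector<int> lab(labels0.begin(), labels0.end());  // 0-based
  std::vector<int> size(Q, 0);
  for (int i = 0; i < n; ++i) {
    if (lab[i] < 0 || lab[i] >= Q) stop("label out of range");
    ++size[lab[i]];
  }
  for (int q = 0; q < Q; ++q)
    if (size[q] == 0) stop("initial labelling leaves domain %d empty", q + 1);

  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* col = Sp + (size_t)i * n;
    for (int j = i + 1; j < n; ++j)
      if (lab[i] == lab[j]) total += col[j];
  }

  std::vector<double> trace;
  if (record_trace) trace.push_back(total);

  long accepted = 0, proposals = 0;
  if (Q > 1) {
    int rejects = 0;
    const long cap = 4000L * (long)n * (long)Q + 100000L;  // safety net
    while (rejects < stall && proposals < cap) {
      if ((proposals & 0x3FF) == 0) Rcpp::checkUserInterrupt();
      ++proposals;
      int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
      const int a = lab[i];
      int d = (int)(unif_rand() * (Q - 1)); if (d >= Q - 1) d = Q - 2;
      if (d >= a) ++d;
      if (size[a] == 1) { ++rejects; continue; }
      const double delta = move_delta(Sp, lab.data(), n, i, a, d);
      if (delta < 0.0) {
        lab[i] = d; --size[a]; ++size[d];
        total += delta; ++accepted; rejects = 0;
        if (record_trace) trace.push_back(total);
      } else {
        ++rejects;
      }
    }
  }

  if (polish && Q > 1) {
    bool changed = true;
    int sweeps = 0;
    std::vector<double> dsum(Q);
    while (changed && sweeps < 200) {
      Rcpp::checkUserInterrupt();
      changed = false; ++sweeps;
      for (int i = 0; i < n; ++i) {
        const int a = lab[i];
        if (size[a] == 1) continue;
        std::fill(dsum.begin(), dsum.end(), 0.0);
        const double* col = Sp + (size_t)i * n;
        for (int j = 0; j < n; ++j)
          if (j != i) dsum[lab[j]] += col[j];
        int best = a; double bestdelta = 0.0;
        for (int d = 0; d < Q; ++d) {
          if (d == a) continue;
          const double delta = dsum[d] - dsum[a];
          if (delta < bestdelta) { bestdelta = delta; best = d; }
        }
        if (best != a) {
          lab[i] = best; --size[a]; ++size[best];
          total += bestdelta; ++accepted; changed = true;
          if (record_trace) trace.push_back(total);
        }
      }
    }
  }

  return List::create(_["labels"] = IntegerVector(lab.begin(), lab.end()),
                      _["total"] = total,
                      _["accepted"] = (double)accepted,
                      _["proposals"] = (double)proposals,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
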