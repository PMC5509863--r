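#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dynamic time alignment kernel between frame ranges [a0, a0+na) and
// [b0, b0+nb) of the frame kernel F (0-based). DP with (1, 2, 1) step
// weights, u(0,0) = 2 f(0,0), tau = u(na-1, nb-1) / (na + nb).
static double dtak_pair(const NumericMatrix &F, int a0, int na, int b0, int nb) {
  std::vector<double> prev(nb), cur(nb);
  const double NEG = -1e300;
  for (int p = 0; p < na; ++p) {
    for (int q = 0; q < nb; ++q) {
      double f = F(a0 + p, b0 + q);
      double best;
      if (p == 0 && q == 0) {
        best = 2.0 * f;
      } else {
        best = NEG;
        if (p > 0 && prev[q] + f > best) best = prev[q] + f;
        if (p > 0 && q > 0 && prev[q - 1] + 2.0 * f > best) best = prev[q - 1] + 2.0 * f;
        if (q > 0 && cur[q - 1] + f > best) best = cur[q - 1] + f;
      }
      cur[q] = best;
    }
    std::swap(prev, cur);
  }
  return prev[nb - 1] / double(na + nb);
}

// [[Rcpp::export(name = ".cpp_dtak")]]
double cpp_dtak(NumericMatrix F, int a0, int na, int b0, int nb) {
  if (na < 1 || nb < 1) stop("segments must be non-empty");
  if (a0 < 0 || b0 < 0 || a0 + na > F.nrow() || b0 + nb > F.nrow())
    stop("segment range outside the kernel");
  return dtak_pair(F, a0, na, b0, nb);
}

// Pairwise DTAK matrix over M segments given by 0-based starts and lengths.
// [[Rcpp::export(name = ".cpp_dtak_matrix")]]
NumericMatrix cpp_dtak_matrix(NumericMatrix F, IntegerVector starts,
                              IntegerVector lens) {
  int M = starts.size();
  NumericMatrix tau(M, M);
  for (int i = 0; i < M; ++i) {
    for (int j = i; j < M; ++j) {
      double v = dtak_pair(F, starts[i], lens[i], starts[j], lens[j]);
      tau(i, j) = v;
      tau(j, i) = v;
    }
  }
  return tau;
}

// Boundary search step of ACA: given the current segmentation (starts, lens,
// labels 0-based) and per-cluster statistics, find boundaries and labels
// minimizing sum_m D^2(Q_m, z_k(m)) by DP over the end frame, with all new
// segment lengths in [l_min, l_max]. ck[k] is the intra-cluster constant
// (1/M_k^2) sum_{j1,j2 in k} tau_{j1 j2}; Mk[k] the cluster sizes.
// unit_len[i] is the frame span of DP position i (all 1 at the frame level;
// level-1 segment lengths when the DP runs on a reduced kernel) and span_max
// caps the total frame span of any new segment.
// Ties: prefer the longer segment, then the smaller k.
// [[Rcpp::export(name = ".cpp_boundary_dp")]]
List cpp_boundary_dp(NumericMatrix F, IntegerVector starts, IntegerVector lens,
                     IntegerVector labels, int K, int l_min, int l_max,
                     NumericVector Mk, NumericVector ck,
                     IntegerVector unit_len, int span_max) {
  const int N = F.nrow();
  const int M = starts.size();
  const double INF = 1e300, NEG = -1e300;

  // Dsq[(a * l_max + (l-1)) * K + k] = D^2 of candidate segment [a, a+l)
  // against cluster k's current centroid
  std::vector<double> Dsq((size_t)N * l_max * K, INF);
  std::vector<double> tau_self(l_max);
  std::vector<double> S((size_t)l_max * K);

  // maxlen[a]: largest unit count l such that segment [a, a+l) spans at most
  // span_max frames
  std::vector<int> maxlen(N);
  for (int a = 0; a < N; ++a) {
    int span = 0, l = 0;
    while (a + l < N && l < l_max && span + unit_len[a + l] <= span_max) {
      span += unit_len[a + l];
      ++l;
    }
    maxlen[a] = l;
  }

  for (int a = 0; a < N; ++a) {
    int La = maxlen[a];
    if (La < 1) stop("a single position exceeds the segment span limit");
    // self-DTAK of [a, a+l) for every l <= La from one incremental DP table
    {
      std::vector<double> u((size_t)La * La);
      for (int p = 0; p < La; ++p) {
        for (int q = 0; q < La; ++q) {
          double f = F(a + p, a + q);
          double best;
          if (p == 0 && q == 0) best = 2.0 * f;
          else {
            best = NEG;
            if (p > 0 && u[(size_t)(p - 1) * La + q] + f > best)
              best = u[(size_t)(p - 1) * La + q] + f;
            if (p > 0 && q > 0 && u[(size_t)(p - 1) * La + q - 1] + 2.0 * f > best)
              best = u[(size_t)(p - 1) * La + q - 1] + 2.0 * f;
            if (q > 0 && u[(size_t)p * La + q - 1] + f > best)
              best = u[(size_t)p * La + q - 1] + f;
          }
          u[(size_t)p * La + q] = best;
        }
      }
      for (int l = 1; l <= La; ++l)
        tau_self[l - 1] = u[(size_t)(l - 1) * La + (l - 1)] / double(2 * l);
    }
    // accumulate (1/M_k) sum_{j in k} tau(candidate, j) for every length
    std::fill(S.begin(), S.begin() + (size_t)La * K, 0.0);
    for (int j = 0; j < M; ++j) {
      int b0 = starts[j], nb = lens[j], k = labels[j];
      if (Mk[k] <= 0) continue;
      std::vector<double> prev(nb), cur(nb);
      for (int p = 0; p < La; ++p) {
        for (int q = 0; q < nb; ++q) {
          double f = F(a + p, b0 + q);
          double best;
          if (p == 0 && q == 0) best = 2.0 * f;
          else {
            best = NEG;
            if (p > 0 && prev[q] + f > best) best = prev[q] + f;
            if (p > 0 && q > 0 && prev[q - 1] + 2.0 * f > best) best = prev[q - 1] + 2.0 * f;
            if (q > 0 && cur[q - 1] + f > best) best = cur[q - 1] + f;
          }
          cur[q] = best;
        }
        std::swap(prev, cur);
        // after row p the candidate has length p+1
        S[(size_t)p * K + k] += (prev[nb - 1] / double(p + 1 + nb)) / Mk[k];
      }
    }
    for (int l = l_min; l <= La; ++l)
      for (int k = 0; k < K; ++k)
        Dsq[((size_t)a * l_max + (l - 1)) * K + k] =
          tau_self[l - 1] - 2.0 * S[(size_t)(l - 1) * K + k] + ck[k];
  }

  // DP over end frame v: V(v) = min_{l, k} V(v - l) + Dsq(v - l, l, k)
  std::vector<double> V(N + 1, INF);
  std::vector<int> bl(N + 1, -1), bk(N + 1, -1);
  V[0] = 0.0;
  for (int v = 1; v <= N; ++v) {
    int lhi = std::min(l_max, v);
    for (int l = lhi; l >= l_min; --l) {  // longer segment preferred on ties
      if (V[v - l] >= INF) continue;
      size_t base = ((size_t)(v - l) * l_max + (l - 1)) * K;
      for (int k = 0; k < K; ++k) {
        double val = V[v - l] + Dsq[base + k];
        if (val < V[v]) { V[v] = val; bl[v] = l; bk[v] = k; }
      }
    }
  }
  if (V[N] >= INF)
    stop("no segmentation with lengths in [l_min, l_max] tiles the series");

  std::vector<int> new_bounds, new_labels;
  for (int v = N; v > 0; v -= bl[v]) {
    new_bounds.push_back(v);
    new_labels.push_back(bk[v]);
  }
  new_bounds.push_back(0);
  std::reverse(new_bounds.begin(), new_bounds.end());
  std::reverse(new_labels.begin(), new_labels.end());

  return List::create(_["boundaries"] = wrap(new_bounds),
                      _["labels"] = wrap(new_labels),
                      _["objective"] = V[N]);
}
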