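#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// Emission density matrix for a Gaussian-emission HMM.
// Masked observations (NA) get likelihood 1 in every state, which
// marginalizes them out of the forward/backward recursions.
static inline double emis(double x, double mean, double sd) {
  if (ISNAN(x)) return 1.0;
  return R::dnorm(x, mean, sd, 0);
}

// Scaled forward-backward pass for one observation series.
// Returns the log-likelihood, per-frame posteriors (gamma) and the
// summed transition posteriors (xi_sum) needed by Baum-Welch.
// [[Rcpp::export]]
List forward_backward_cpp(NumericVector obs, NumericVector means,
                          NumericVector sds, NumericMatrix trans,
                          NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), e(T, K);
  NumericMatrix xi_sum(K, K);
  NumericVector c(T);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) e(t, k) = emis(obs[t], means[k], sds[k]);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * e(0, k); s += alpha(0, k); }
  if (s <= 0) stop("zero likelihood at frame 1; check emission parameters");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
      alpha(t, j) = a * e(t, j);
      s += alpha(t, j);
    }
    if (s <= 0) stop("zero likelihood at frame %d; check emission parameters", t + 1);
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += trans(i, j) * e(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    NumericMatrix xi(K, K);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        xi(i, j) = alpha(t, i) * trans(i, j) * e(t + 1, j) * beta(t + 1, j);
        z += xi(i, j);
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi_sum(i, j) += xi(i, j) / z;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi_sum);
}

// Most probable state path (Viterbi) in log space.
// Ties are broken toward the lowest state index.
// [[Rcpp::export]]
List viterbi_cpp(NumericVector obs, NumericVector means, NumericVector sds,
                 NumericMatrix trans, NumericVector init) {
  const int T = obs.size(), K = means.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -std::numeric_limits<double>::infinity();

  auto lemis = [&](int t, int k) {
    double d = emis(obs[t], means[k], sds[k]);
    return d > 0 ? std::log(d) : NEG;
  };
  for (int k = 0; k < K; ++k)
    delta(0, k) = (init[k] > 0 ? std::log(init[k]) : NEG) + lemis(0, k);

  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      double best = NEG; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + (trans(i, j) > 0 ? std::log(trans(i, j)) : NEG);
        if (v > best) { best = v; arg = i; }   // strict >: first (lowest) index wins ties
      }
      delta(t, j) = best + lemis(t, j);
      psi(t, j) = arg;
    }

  IntegerVector path(T);
  double best = NEG; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states for R
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Simulate a discrete-time Markov chain using R's RNG stream so that
// set.seed() in R controls the draw.
// [[Rcpp::export]]
IntegerVector sim_markov_cpp(int n, NumericMatrix trans, NumericVector init) {
  const int K = init.size();
  IntegerVector out(n);
  RNGScope scope;
  double u = unif_rand(), acc = 0.0;
  int s = K - 1;
  for (int k = 0; k < K; ++k) { acc += init[k]; if (u <= acc) { s = k; break; } }
  out[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    u = unif_rand(); acc = 0.0;
    int nxt = K - 1;
    for (int k = 0; k < K; ++k) { acc += trans(s, k); if (u <= acc) { nxt = k; break; } }
    s = nxt;
    out[t] = s + 1;
  }
  return out;
}

// Mean-shift change points by binary segmentation.  A split is accepted
// when the absolute difference between the two segment means exceeds
// `thresh`; segments shorter than `min_seg` are never split.  Returns the
// 1-based index of the first frame right of each change point, plus the
// signed local mean shift (right minus left, over the parent segment).
// [[Rcpp::export]]
List find_steps_cpp(NumericVector x, double thresh, int min_seg) {
  const int n = x.size();
  std::vector<int> cps;
  std::vector<double> shifts;
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];

  std::stack<std::pair<int, int> > todo;  // 0-based inclusive ranges
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int lo = todo.top().first, hi = todo.top().second;
    todo.pop();
    int len = hi - lo + 1;
    if (len < 2 * min_seg) continue;
    // split location by the weighted CUSUM statistic (avoids favouring
    // short extreme segments); acceptance threshold on the raw mean shift
    double best = 0.0; int bt = -1; double bshift = 0.0;
    for (int t = lo + min_seg - 1; t <= hi - min_seg; ++t) {
      double nL = t - lo + 1, nR = hi - t;
      double mL = (S[t + 1] - S[lo]) / nL;
      double mR = (S[hi + 1] - S[t + 1]) / nR;
      double d = std::sqrt(nL * nR / len) * std::fabs(mL - mR);
      if (d > best) { best = d; bt = t; bshift = mR - mL; }
    }
    if (bt >= 0) {
      double nL = bt - lo + 1, nR = hi - bt;
      double mL = (S[bt + 1] - S[lo]) / nL;
      double mR = (S[hi + 1] - S[bt + 1]) / nR;
      if (std::fabs(mL - mR) <= thresh) bt = -1;
    }
    if (bt >= 0) {
      cps.push_back(bt + 2);  // 1-based first frame of the right segment
      shifts.push_back(bshift);
      todo.push(std::make_pair(lo, bt));
      todo.push(std::make_pair(bt + 1, hi));
    }
  }
  // sort by position
  std::vector<size_t> ord(cps.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return cps[a] < cps[b]; });
  IntegerVector cp_out(cps.size());
  NumericVector sh_out(cps.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    cp_out[i] = cps[ord[i]];
    sh_out[i] = shifts[ord[i]];
  }
  return List::create(_["changepoint"] = cp_out, _["shift"] = sh_out);
}

// ---- batched variants over concatenated series ----------------------------
// `lengths[i]` frames of series i are stored consecutively in `obs`.

static void fb_core(const double* obs, int T, int K,
                    const NumericVector& means, const NumericVector& sds,
                    const NumericMatrix& trans, const NumericVector& init,
                    double& ll, NumericMatrix& xi_sum, NumericVector& g1,
                    NumericVector& w, NumericVector& wx, NumericVector& wx2,
                    bool moments) {
  std::vector<double> alpha(T * K), beta(T * K), e(T * K), c(T);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) e[t * K + k] = emis(obs[t], means[k], sds[k]);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = init[k] * e[k]; s += alpha[k]; }
  if (s <= 0) stop("zero likelihood at frame 1; check emission parameters");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha[(t - 1) * K + i] * trans(i, j);
      alpha[t * K + j] = a * e[t * K + j];
      s += alpha[t * K + j];
    }
    if (s <= 0) stop("zero likelihood; check emission parameters");
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha[t * K + j] /= s;
  }
  for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += trans(i, j) * e[(t + 1) * K + j] * beta[(t + 1) * K + j];
      beta[t * K + i] = b / c[t + 1];
    }
  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    double xi[9];  // K <= 3 here; guard anyway
    std::vector<double> xibuf;
    double* xp = xi;
    if (K > 3) { xibuf.resize(K * K); xp = xibuf.data(); }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = alpha[t * K + i] * trans(i, j) *
          e[(t + 1) * K + j] * beta[(t + 1) * K + j];
        xp[i * K + j] = v;
        z += v;
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi_sum(i, j) += xp[i * K + j] / z;
  }
  // gamma for frame 1 and (optionally) observation moments
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    double gv[8];
    for (int k = 0; k < K; ++k) { gv[k] = alpha[t * K + k] * beta[t * K + k]; g += gv[k]; }
    for (int k = 0; k < K; ++k) gv[k] /= g;
    if (t == 0) for (int k = 0; k < K; ++k) g1[k] += gv[k];
    if (moments && !ISNAN(obs[t])) {
      for (int k = 0; k < K; ++k) {
        w[k] += gv[k];
        wx[k] += gv[k] * obs[t];
        wx2[k] += gv[k] * obs[t] * obs[t];
      }
    }
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
}

// One Baum-Welch E-step over all series at once.
// [[Rcpp::export]]
List em_accum_cpp(NumericVector obs, IntegerVector lengths,
                  NumericVector means, NumericVector sds,
                  NumericMatrix trans, NumericVector init, bool moments) {
  const int K = means.size();
  if (K > 8) stop("batched EM supports at most 8 states");
  double ll = 0.0;
  NumericMatrix xi_sum(K, K);
  NumericVector g1(K), w(K), wx(K), wx2(K);
  int off = 0;
  for (int s = 0; s < lengths.size(); ++s) {
    fb_core(REAL(obs) + off, lengths[s], K, means, sds, trans, init,
            ll, xi_sum, g1, w, wx, wx2, moments);
    off += lengths[s];
  }
  return List::create(_["loglik"] = ll, _["xi_sum"] = xi_sum, _["g1"] = g1,
                      _["w"] = w, _["wx"] = wx, _["wx2"] = wx2);
}

// Viterbi over concatenated series; returns concatenated 1-based paths.
// [[Rcpp::export]]
IntegerVector viterbi_batch_cpp(NumericVector obs, IntegerVector lengths,
                                NumericVector means, NumericVector sds,
                                NumericMatrix trans, NumericVector init) {
  IntegerVector out(obs.size());
  int off = 0;
  for (int s = 0; s < lengths.size(); ++s) {
    NumericVector sub(lengths[s]);
    for (int t = 0; t < lengths[s]; ++t) sub[t] = obs[off + t];
    List v = viterbi_cpp(sub, means, sds, trans, init);
    IntegerVector path = v["path"];
    for (int t = 0; t < lengths[s]; ++t) out[off + t] = path[t];
    off += lengths[s];
  }
  return out;
}
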