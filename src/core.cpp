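#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Numerically stable logistic; evaluated branch-wise so large |s| never
// overflows exp().
static inline double sigmoid(double s) {
  if (s >= 0.0) return 1.0 / (1.0 + std::exp(-s));
  double e = std::exp(s);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix W, NumericVector h, int nSteps, double pMax,
                  Nullable<IntegerMatrix> stim, IntegerVector x0,
                  bool recordInputs) {
  int nrec = W.nrow(), ntot = W.ncol(), next_ = ntot - nrec;
  if ((int)x0.size() != ntot) stop("initial state length must equal total neuron count");
  IntegerMatrix spikes(nSteps, ntot);
  NumericMatrix inputs = recordInputs ? NumericMatrix(nSteps, nrec) : NumericMatrix(0, 0);
  IntegerMatrix stimM;
  bool haveStim = stim.isNotNull();
  if (haveStim) {
    stimM = as<IntegerMatrix>(stim);
    if (stimM.nrow() < nSteps || stimM.ncol() != next_)
      stop("stimulus matrix must have nSteps rows and one column per external neuron");
  } else if (next_ > 0) {
    stop("network has external neurons but no stimulus was supplied");
  }

  IntegerVector x = clone(x0);
  NumericVector s(nrec);
  const double* wp = &W(0, 0);
  std::vector<double> hv(h.begin(), h.end());
  std::vector<int> xc(x.begin(), x.end());
  std::vector<double> sv(nrec);
  auto minput = [&]() {
    for (int i = 0; i < nrec; ++i) sv[i] = -hv[i];
    for (int j = 0; j < ntot; ++j) if (xc[j]) {
      const double* col = wp + (size_t)j * nrec;
      for (int i = 0; i < nrec; ++i) sv[i] += col[i];
    }
  };
  minput(); // s(x^0), generates x^1
  for (int t = 0; t < nSteps; ++t) {
    for (int i = 0; i < nrec; ++i) {
      double p = pMax * sigmoid(sv[i]);
      xc[i] = (unif_rand() < p) ? 1 : 0;
    }
    for (int k = 0; k < next_; ++k) {
      int v = stimM(t, k);
      if (v != 0 && v != 1) stop("stimulus entries must be 0 or 1");
      xc[nrec + k] = v;
    }
    for (int j = 0; j < ntot; ++j) if (xc[j]) spikes(t, j) = 1; // sparse write
    minput(); // s^t, generates x^{t+1}
    if (recordInputs) for (int i = 0; i < nrec; ++i) inputs(t, i) = sv[i];
  }
  for (int j = 0; j < ntot; ++j) x[j] = xc[j];
  for (int i = 0; i < nrec; ++i) s[i] = sv[i];
  return List::create(_["spikes"] = spikes,
                      _["inputs"] = recordInputs ? (SEXP)inputs : R_NilValue,
                      _["xFinal"] = x, _["sFinal"] = s);
}

// One chunk of the learning schedule. State (parameters, network state,
// traces) is passed in, cloned, advanced nSteps, and returned, so the R
// driver can log metrics, snapshot, and resume between chunks without
// perturbing the random stream.
//
// Per-step schedule (strictly causal leaky averages):
//  entering the step we hold x = x^t and sPrev = s^{t-1} (which generated
//  the recurrent part of x^t), tau-traces through (psi^{t-1}, x^{t-1}) and
//  T-averages through step t-1.
//  (1) s^t from x^t; (2) global signals from x^t, sPrev, s^t and the
//  T-averages; (3) apply the two-term updates to masked entries;
//  (4) sample x^{t+1} from s^t; (5) psi^t and tau-trace update with
//  (psi^t, x^t); (6) T-average update with step-t quantities.
// [[Rcpp::export]]
List cpp_train_chunk(NumericMatrix W_, NumericVector h_, IntegerVector x_,
                     NumericVector sPrev_, IntegerVector xPrevRec_,
                     NumericMatrix eligPair_, NumericVector eligPost_,
                     double avgM, NumericVector avgFire_, NumericVector avgLS_,
                     double pMax, double p0, double epsilon,
                     double kappa, double eta, double zeta,
                     double tau, double Tavg, double delta,
                     int variant, // 0 = standard, 1 = a-prime
                     LogicalVector scope_, LogicalVector rowMask_, LogicalVector colMask_,
                     int nSteps, Nullable<IntegerMatrix> stim,
                     bool freeze, bool collectCov) {
  int nrec = W_.nrow(), ntot = W_.ncol(), next_ = ntot - nrec;
  NumericMatrix W = clone(W_);
  NumericVector h = clone(h_);
  IntegerVector x = clone(x_);
  NumericVector sPrev = clone(sPrev_);
  IntegerVector xPrev = clone(xPrevRec_);
  NumericMatrix eligPair = clone(eligPair_);
  NumericVector eligPost = clone(eligPost_);
  NumericVector avgFire = clone(avgFire_);
  NumericVector avgLS = clone(avgLS_);
  LogicalVector scope = scope_, rowMask = rowMask_, colMask = colMask_;

  IntegerMatrix stimM;
  bool haveStim = stim.isNotNull();
  if (haveStim) {
    stimM = as<IntegerMatrix>(stim);
    if (stimM.nrow() < nSteps || stimM.ncol() != next_)
      stop("stimulus matrix must have nSteps rows and one column per external neuron");
  } else if (next_ > 0) {
    stop("network has external neurons but no stimulus was supplied");
  }

  double s0 = std::log(p0 / (pMax - p0));
  double decT = 1.0 - 1.0 / Tavg, decTau = 1.0 - 1.0 / tau;

  NumericVector sNow(nrec), lr(nrec), psi(nrec);
  NumericMatrix updW(freeze ? nrec : 0, freeze ? ntot : 0);
  NumericVector updH(freeze ? nrec : 0);

  // covariance sufficient statistics for the Gaussian MI estimate:
  // z = (x^t_rec, x^{t-1}_rec), accumulated sparsely
  int zdim = 2 * nrec;
  NumericVector covS1(collectCov ? zdim : 0);
  NumericMatrix covS2(collectCov ? zdim : 0, collectCov ? zdim : 0);
  long covN = 0;

  double sumM = 0.0, sumG1 = 0.0, sumG2 = 0.0, sumG3 = 0.0, sumG4 = 0.0;
  bool diverged = false;
  int stepsDone = 0;
  std::vector<int> onIdx; onIdx.reserve(2 * nrec);
  std::vector<int> xc(x.begin(), x.end()), xn(ntot);

  for (int t = 0; t < nSteps; ++t) {
    // (1) membrane inputs from the current state
    {
      for (int i = 0; i < nrec; ++i) sNow[i] = -h[i];
      for (int j = 0; j < ntot; ++j) if (xc[j]) {
        const double* col = &W(0, j);
        for (int i = 0; i < nrec; ++i) sNow[i] += col[i];
      }
    }

    // (2) global signals
    double m = 0.0;
    for (int i = 0; i < nrec; ++i) if (scope[i] && xc[i]) m += 1.0;
    double g1 = 0.0, sumLR = 0.0, sumAvgLS = 0.0;
    for (int i = 0; i < nrec; ++i) {
      if (!scope[i]) { lr[i] = 0.0; continue; }
      double sg = pMax * sigmoid(sPrev[i]);
      double pe = xc[i] ? sg : 1.0 - sg;
      if (pe < 1e-300) pe = 1e-300;
      double Z = xc[i] ? avgFire[i] : 1.0 - avgFire[i];
      if (Z <= delta) Z = delta; // removes the cold-start / rare-event singularity
      lr[i] = std::log(pe) - std::log(Z);
      if (variant == 0) {
        double den = (avgLS[i] <= delta) ? delta : avgLS[i];
        g1 += lr[i] / den;
      } else {
        sumLR += lr[i];
        sumAvgLS += avgLS[i];
      }
    }
    if (variant == 1) {
      double den = (sumAvgLS <= delta) ? delta : sumAvgLS;
      g1 = sumLR / den;
    }
    double g2 = kappa * (0.5 * m * (m - 1.0) - (avgM - p0) * m);
    double g3 = 0.0, g4 = 0.0;
    for (int i = 0; i < nrec; ++i) {
      if (!scope[i]) continue;
      if (xc[i]) g3 += avgFire[i] - p0;
      double d = sNow[i] - s0;
      g4 += d * d;
    }
    g3 *= eta;
    g4 *= 0.5 * zeta;
    double G = g1 - g2 - g3 - g4;
    sumM += m; sumG1 += g1; sumG2 += g2; sumG3 += g3; sumG4 += g4;
    if (!std::isfinite(G)) { diverged = true; stepsDone = t; break; }

    // (3) parameter update (or accumulation of the would-be update)
    if (freeze) {
      double a = tau * G;
      for (int j = 0; j < ntot; ++j) {
        if (!colMask[j]) continue;
        const double* ec = &eligPair(0, j);
        double* uc = &updW(0, j);
        for (int i = 0; i < nrec; ++i) if (rowMask[i] && i != j) uc[i] += a * ec[i];
        if (xc[j]) {
          for (int i = 0; i < nrec; ++i)
            if (rowMask[i] && i != j) uc[i] -= zeta * (sNow[i] - s0);
        }
      }
      for (int i = 0; i < nrec; ++i)
        if (rowMask[i]) updH[i] += -a * eligPost[i] + zeta * (sNow[i] - s0);
    } else if (epsilon != 0.0) {
      double a = epsilon * (tau / Tavg) * G;
      double b = epsilon * (zeta / Tavg);
      for (int j = 0; j < ntot; ++j) {
        if (!colMask[j]) continue;
        const double* ec = &eligPair(0, j);
        double* wc = &W(0, j);
        if (xc[j]) {
          for (int i = 0; i < nrec; ++i)
            if (rowMask[i] && i != j) wc[i] += a * ec[i] - b * (sNow[i] - s0);
        } else {
          for (int i = 0; i < nrec; ++i)
            if (rowMask[i] && i != j) wc[i] += a * ec[i];
        }
      }
      for (int i = 0; i < nrec; ++i)
        if (rowMask[i]) h[i] += -a * eligPost[i] + b * (sNow[i] - s0);
    }

    // (4) sample the next state
    for (int i = 0; i < nrec; ++i) {
      double p = pMax * sigmoid(sNow[i]);
      xn[i] = (unif_rand() < p) ? 1 : 0;
    }
    for (int k = 0; k < next_; ++k) {
      int v = stimM(t, k);
      if (v != 0 && v != 1) stop("stimulus entries must be 0 or 1");
      xn[nrec + k] = v;
    }

    // (5) psi^t and tau-trace update with (psi^t, x^t)
    for (int i = 0; i < nrec; ++i) {
      double sg = sigmoid(sNow[i]);
      if (xn[i]) {
        psi[i] = 1.0 - sg;
      } else {
        double den = 1.0 - pMax * sg;
        if (den <= 0.0) stop("psi undefined: pMax*sigma(s) reached 1 with a silent outcome");
        psi[i] = -pMax * sg * (1.0 - sg) / den;
      }
    }
    for (int j = 0; j < ntot; ++j) {
      double* ec = &eligPair(0, j);
      if (xc[j]) {
        for (int i = 0; i < nrec; ++i) ec[i] = decTau * ec[i] + psi[i] / tau;
      } else {
        for (int i = 0; i < nrec; ++i) ec[i] *= decTau;
      }
    }
    for (int i = 0; i < nrec; ++i) eligPost[i] = decTau * eligPost[i] + psi[i] / tau;

    // (6) T-averages with step-t quantities
    avgM = m / Tavg + decT * avgM;
    for (int i = 0; i < nrec; ++i) {
      avgFire[i] = pMax * sigmoid(sNow[i]) / Tavg + decT * avgFire[i];
      avgLS[i] = lr[i] / Tavg + decT * avgLS[i];
    }

    // covariance stats on (x^t, x^{t-1}); sparse rank-1 accumulation
    if (collectCov) {
      onIdx.clear();
      for (int i = 0; i < nrec; ++i) if (xc[i]) onIdx.push_back(i);
      for (int i = 0; i < nrec; ++i) if (xPrev[i]) onIdx.push_back(nrec + i);
      for (size_t a2 = 0; a2 < onIdx.size(); ++a2) {
        covS1[onIdx[a2]] += 1.0;
        for (size_t b2 = 0; b2 < onIdx.size(); ++b2) covS2(onIdx[a2], onIdx[b2]) += 1.0;
      }
      ++covN;
    }

    // advance (copy by value: sNow is recomputed in place next iteration)
    for (int i = 0; i < nrec; ++i) { xPrev[i] = xc[i]; sPrev[i] = sNow[i]; }
    std::swap(xc, xn);
    stepsDone = t + 1;
  }

  for (int j = 0; j < ntot; ++j) x[j] = xc[j];
  if (!diverged) {
    for (int j = 0; j < ntot && !diverged; ++j)
      for (int i = 0; i < nrec; ++i)
        if (!std::isfinite(W(i, j))) { diverged = true; break; }
    for (int i = 0; i < nrec; ++i) if (!std::isfinite(h[i])) diverged = true;
  }

  return List::create(
    _["weights"] = W, _["thresholds"] = h,
    _["x"] = x, _["sPrev"] = sPrev, _["xPrevRec"] = xPrev,
    _["eligPair"] = eligPair, _["eligPost"] = eligPost,
    _["avgM"] = avgM, _["avgFire"] = avgFire, _["avgLS"] = avgLS,
    _["updW"] = freeze ? (SEXP)updW : R_NilValue,
    _["updH"] = freeze ? (SEXP)updH : R_NilValue,
    _["covS1"] = collectCov ? (SEXP)covS1 : R_NilValue,
    _["covS2"] = collectCov ? (SEXP)covS2 : R_NilValue,
    _["covN"] = (double)covN,
    _["meanM"] = sumM / std::max(stepsDone, 1),
    _["meanGamma"] = NumericVector::create(sumG1, sumG2, sumG3, sumG4) / std::max(stepsDone, 1),
    _["diverged"] = diverged, _["stepsDone"] = stepsDone);
}

// Leaky integrate-and-fire neuron driven by a constant current plus Wiener
// noise, integrated by Euler-Maruyama; returns firing frequency per current.
// [[Rcpp::export]]
NumericVector cpp_lif_fi(NumericVector currents, double tauM, double theta,
                         double vRest, double D, double tRef, double dt,
                         double duration) {
  int nI = currents.size();
  NumericVector freq(nI);
  long nSteps = (long)std::floor(duration / dt);
  long refSteps = (long)std::round(tRef / dt);
  double sqdt = std::sqrt(dt);
  for (int k = 0; k < nI; ++k) {
    double I = currents[k], V = vRest;
    long spikes = 0;
    for (long t = 0; t < nSteps; ++t) {
      V += (dt / tauM) * (-V + vRest + I);
      if (D > 0.0) V += (D / tauM) * sqdt * norm_rand();
      if (V > theta) {
        ++spikes;
        V = vRest;
        t += refSteps; // held at rest for the refractory period
      }
    }
    freq[k] = (double)spikes / duration;
  }
  return freq;
}

// Simulation recording only per-step population spike counts (for avalanche
// statistics at long horizons, where the full raster would not fit memory).
// [[Rcpp::export]]
IntegerVector cpp_simulate_counts(NumericMatrix W, NumericVector h, int nSteps,
                                  double pMax, IntegerVector x0) {
  int nrec = W.nrow(), ntot = W.ncol();
  if (ntot != nrec) stop("count-only simulation supports recurrent-only networks");
  IntegerVector counts(nSteps);
  const double* wp = &W(0, 0);
  std::vector<double> hv(h.begin(), h.end());
  std::vector<int> xc(x0.begin(), x0.end());
  std::vector<double> sv(nrec);
  auto minput = [&]() {
    for (int i = 0; i < nrec; ++i) sv[i] = -hv[i];
    for (int j = 0; j < ntot; ++j) if (xc[j]) {
      const double* col = wp + (size_t)j * nrec;
      for (int i = 0; i < nrec; ++i) sv[i] += col[i];
    }
  };
  minput();
  for (int t = 0; t < nSteps; ++t) {
    int m = 0;
    for (int i = 0; i < nrec; ++i) {
      double p = pMax * sigmoid(sv[i]);
      xc[i] = (unif_rand() < p) ? 1 : 0;
      m += xc[i];
    }
    counts[t] = m;
    minput();
  }
  return counts;
}

// Avalanche catalog at long horizons: simulates the dynamics but returns
// only burst sizes and durations.  Silent stretches are skipped exactly:
// conditioned on a silent step (and uniform thresholds), the dynamics are
// memoryless, so the number of silent steps before the next initiation is
// geometric and the initiating spike set is an (at least one) conditioned
// Bernoulli draw.  Clusters touching either end of the horizon are
// discarded as censored.
// [[Rcpp::export]]
List cpp_avalanche_catalog(NumericMatrix W, NumericVector h, double nSteps,
                           double pMax) {
  int nrec = W.nrow();
  if (W.ncol() != nrec) stop("avalanche catalog supports recurrent-only networks");
  for (int i = 1; i < nrec; ++i)
    if (h[i] != h[0]) stop("silent-gap skipping requires uniform thresholds");
  double psp = pMax * sigmoid(-h[0]);
  if (psp <= 0 || psp >= 1) stop("spontaneous rate must lie in (0,1)");
  double q = 1.0 - std::pow(1.0 - psp, nrec); // P(at least one spontaneous spike)
  // conditional spike-count distribution at an initiation step
  std::vector<double> cum(nrec + 1, 0.0);
  {
    double logp = std::log(psp), log1p_ = std::log(1.0 - psp);
    double acc = 0.0;
    for (int m = 1; m <= nrec; ++m) {
      double lc = R::lchoose(nrec, m) + m * logp + (nrec - m) * log1p_;
      acc += std::exp(lc) / q;
      cum[m] = acc;
    }
  }
  const double* wp = &W(0, 0);
  std::vector<int> xc(nrec, 0);
  std::vector<double> sv(nrec);
  std::vector<int> sizes, durations;
  sizes.reserve(1 << 16); durations.reserve(1 << 16);
  double t = 0.0;
  long curSize = 0, curDur = 0;
  // the run starts silent, so the first cluster is never left-censored
  while (t < nSteps) {
    int m = 0;
    for (int i = 0; i < nrec; ++i) m += xc[i];
    if (m == 0) {
      if (curSize > 0) { // a silent step closes the cluster
        sizes.push_back((int)curSize); durations.push_back((int)curDur);
        curSize = 0; curDur = 0;
      }
      // geometric silent gap, then a conditioned initiation
      double u = unif_rand();
      double gap = std::floor(std::log(u) / std::log(1.0 - q));
      t += gap + 1.0;
      if (t >= nSteps) break;
      double v = unif_rand();
      int mNew = 1;
      while (mNew < nrec && v > cum[mNew]) ++mNew;
      // choose which neurons fired, uniformly without replacement
      std::fill(xc.begin(), xc.end(), 0);
      int placed = 0;
      while (placed < mNew) {
        int idx = (int)(unif_rand() * nrec);
        if (idx >= nrec) idx = nrec - 1;
        if (!xc[idx]) { xc[idx] = 1; ++placed; }
      }
      curSize = mNew; curDur = 1;
    } else {
      // ordinary step
      for (int i = 0; i < nrec; ++i) sv[i] = -h[i];
      for (int j = 0; j < nrec; ++j) if (xc[j]) {
        const double* col = wp + (size_t)j * nrec;
        for (int i = 0; i < nrec; ++i) sv[i] += col[i];
      }
      int mNext = 0;
      for (int i = 0; i < nrec; ++i) {
        double p = pMax * sigmoid(sv[i]);
        xc[i] = (unif_rand() < p) ? 1 : 0;
        mNext += xc[i];
      }
      t += 1.0;
      if (mNext > 0) { curSize += mNext; curDur += 1; }
    }
  }
  // an unfinished cluster at the right edge is censored and discarded
  return List::create(_["sizes"] = wrap(sizes), _["durations"] = wrap(durations),
                      _["steps"] = t);
}
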