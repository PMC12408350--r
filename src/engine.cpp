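// Core numerical engine: likelihood and gradients of the latent Langevin
// model with spike-emission decay and absorbing boundaries, continuous-state
// Viterbi decoding, and the Euler-Maruyama trial simulator.
//
// All propagators act in the eigenbasis of the interior generator H
// (densities pinned to zero at the domain boundaries), so exp(-H dt) is
// applied exactly for arbitrary inter-spike intervals. Eigen-decompositions
// are computed in R (base eigen) and passed in as complex matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Action of exp(-H dt) on a real vector, given eigen pieces of H.
static vec prop_vec(const cx_mat& V, const cx_mat& Vinv, const cx_vec& mu,
                    const vec& p, double dt) {
  cx_vec w = Vinv * cx_vec(p, vec(p.n_elem, fill::zeros));
  w %= exp(-mu * dt);
  return real(V * w);
}

// Value-only pass over a batch of trials sharing one generator; avoids
// per-trial R call overhead. Returns per-trial log-likelihoods.
// [[Rcpp::export]]
Rcpp::NumericVector fp_batch_loglik_cpp(const arma::cx_mat& V, const arma::cx_mat& Vinv,
                                        const arma::cx_vec& mu, const arma::vec& wint,
                                        const arma::vec& p0int, const arma::mat& fint,
                                        const arma::vec& atot,
                                        const Rcpp::List& trials) {
  int K = trials.size();
  Rcpp::NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    Rcpp::List tr = trials[k];
    vec dts = Rcpp::as<vec>(tr["dts"]);
    ivec ids = Rcpp::as<ivec>(tr["ids"]);
    int N = ids.n_elem;
    vec p = p0int;
    double logl = 0.0;
    bool bad = false;
    for (int j = 0; j <= N; ++j) {
      p = prop_vec(V, Vinv, mu, p, dts(j));
      double c = dot(wint, p);
      if (!(c > 0.0) || !std::isfinite(c)) { bad = true; break; }
      p /= c;
      logl += std::log(c);
      if (j < N) {
        p %= fint.col(ids(j));
        double e = dot(wint, p);
        if (!(e > 0.0) || !std::isfinite(e)) { bad = true; break; }
        p /= e;
        logl += std::log(e);
      }
    }
    if (bad) { out[k] = R_NegInf; continue; }
    double a = dot(atot, p);
    out[k] = (a > 0.0 && std::isfinite(a)) ? logl + std::log(a) : R_NegInf;
  }
  return out;
}

// Full-trial forward pass. Returns the log of
//   a' K(dE) L_N K(dN) ... L_1 K(d1) p0
// with per-factor rescaling. dts has N+1 entries (ISIs then final interval),
// ids has N entries (0-based neuron index per spike).
// [[Rcpp::export]]
double fp_trial_loglik_cpp(const arma::cx_mat& V, const arma::cx_mat& Vinv,
                           const arma::cx_vec& mu, const arma::vec& wint,
                           const arma::vec& p0int, const arma::mat& fint,
                           const arma::vec& atot,
                           const arma::vec& dts, const arma::ivec& ids) {
  int N = ids.n_elem;
  vec p = p0int;
  double logl = 0.0;
  for (int j = 0; j <= N; ++j) {
    p = prop_vec(V, Vinv, mu, p, dts(j));
    double c = dot(wint, p);
    if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
    p /= c;
    logl += std::log(c);
    if (j < N) {
      p %= fint.col(ids(j));
      double e = dot(wint, p);
      if (!(e > 0.0) || !std::isfinite(e)) return R_NegInf;
      p /= e;
      logl += std::log(e);
    }
  }
  double a = dot(atot, p);
  if (!(a > 0.0) || !std::isfinite(a)) return R_NegInf;
  return logl + std::log(a);
}

// Per-trial left/right absorption weights at the trial end (used for choice
// prediction from the filtered density and for diagnostics).
// [[Rcpp::export]]
Rcpp::NumericVector fp_trial_absorb_cpp(const arma::cx_mat& V, const arma::cx_mat& Vinv,
                                        const arma::cx_vec& mu, const arma::vec& wint,
                                        const arma::vec& p0int, const arma::mat& fint,
                                        const arma::vec& aL, const arma::vec& aR,
                                        const arma::vec& dts, const arma::ivec& ids) {
  int N = ids.n_elem;
  vec p = p0int;
  for (int j = 0; j <= N; ++j) {
    p = prop_vec(V, Vinv, mu, p, dts(j));
    double c = dot(wint, p);
    if (!(c > 0.0) || !std::isfinite(c)) return Rcpp::NumericVector::create(NA_REAL, NA_REAL);
    p /= c;
    if (j < N) {
      p %= fint.col(ids(j));
      double e = dot(wint, p);
      if (!(e > 0.0) || !std::isfinite(e)) return Rcpp::NumericVector::create(NA_REAL, NA_REAL);
      p /= e;
    }
  }
  double wl = std::max(dot(aL, p), 0.0), wr = std::max(dot(aR, p), 0.0);
  return Rcpp::NumericVector::create(wl, wr);
}

// Forward-backward pass over a batch of trials sharing one generator.
// Returns the summed log-likelihood and the gradients of the summed
// log-likelihood with respect to: the generator matrix H (matrix G), the
// tuning rates at interior nodes through the emission factors (demis, one
// column per neuron; the decay-term contribution diag(G) is added in R), and
// the initial interior density (dp0). Gradient chain rules to the auxiliary
// parametrization are applied in R.
// The propagator gradient uses the Frechet derivative of exp(-H dt) in the
// eigenbasis: the divided-difference factor splits as
// Psi(a,b) = (ea(a) - ea(b)) / (mu(a) - mu(b))
//          = [ea(a) * 1 - 1 * ea(b)] .* invd(a,b),
// where invd is fixed for the whole batch, so all per-interval rank-one
// contributions accumulate into two complex GEMMs. (Near-)degenerate
// eigenvalue pairs get the analytic limit -dt * exp(-mu dt) separately.
// [[Rcpp::export]]
Rcpp::List fp_batch_grad_cpp(const arma::cx_mat& V, const arma::cx_mat& Vinv,
                             const arma::cx_vec& mu, const arma::vec& wint,
                             const arma::vec& p0int, const arma::mat& fint,
                             const arma::vec& atot,
                             const Rcpp::List& trials) {
  int nint = p0int.n_elem, M = fint.n_cols, K = trials.size();
  mat demis(nint, M, fill::zeros);
  vec dp0(nint, fill::zeros);
  double logl_total = 0.0;
  int n_ok = 0;
  cx_mat Vt = V.st();        // plain transposes (no conjugation)
  cx_mat Vinvt = Vinv.st();

  // per-batch divided-difference reciprocals and degenerate-pair list
  cx_mat invd(nint, nint, fill::zeros);
  std::vector<std::pair<int, int>> deg;
  for (int b = 0; b < nint; ++b) {
    for (int a = 0; a < nint; ++a) {
      cx_double d = mu(a) - mu(b);
      if (std::abs(d) < 1e-9 * (1.0 + std::abs(mu(a)))) {
        deg.push_back(std::make_pair(a, b));
      } else {
        invd(a, b) = cx_double(1.0, 0.0) / d;
      }
    }
  }

  // ISI-wise factors collected for the batch-level GEMMs
  int total_isi = 0;
  for (int k = 0; k < K; ++k) {
    Rcpp::List tr = trials[k];
    total_isi += Rcpp::as<ivec>(tr["ids"]).n_elem + 1;
  }
  cx_mat U1(nint, total_isi), U2(nint, total_isi), W1(nint, total_isi), W2(nint, total_isi);
  cx_mat Mdeg(nint, nint, fill::zeros);
  int col = 0;

  for (int k = 0; k < K; ++k) {
    Rcpp::List tr = trials[k];
    vec dts = Rcpp::as<vec>(tr["dts"]);
    ivec ids = Rcpp::as<ivec>(tr["ids"]);
    int N = ids.n_elem;

    // forward
    mat PK(nint, N + 1);       // normalized state after propagator j
    cx_mat Wv(nint, N + 1);    // eigen coords of the state entering propagator j
    cx_mat Ea(nint, N + 1);    // exp(-mu * dt_j)
    vec nrm(N + 1);
    vec p = p0int;
    double logl = 0.0;
    bool bad = false;
    for (int j = 0; j <= N; ++j) {
      cx_vec coords = Vinv * cx_vec(p, vec(nint, fill::zeros));
      Wv.col(j) = coords;
      Ea.col(j) = exp(-mu * dts(j));
      vec q = real(V * (coords % Ea.col(j)));
      double c = dot(wint, q);
      if (!(c > 0.0) || !std::isfinite(c)) { bad = true; break; }
      q /= c;
      nrm(j) = c;
      logl += std::log(c);
      PK.col(j) = q;
      if (j < N) {
        q %= fint.col(ids(j));
        double e = dot(wint, q);
        if (!(e > 0.0) || !std::isfinite(e)) { bad = true; break; }
        q /= e;
        logl += std::log(e);
      }
      p = q;
    }
    if (bad) continue;
    double afin = dot(atot, PK.col(N));
    if (!(afin > 0.0) || !std::isfinite(afin)) continue;
    logl += std::log(afin);
    logl_total += logl;
    ++n_ok;

    // backward adjoints; q covers all factors after propagator j at the top
    // of each iteration
    vec q = atot;
    for (int j = N; j >= 0; --j) {
      cx_vec wq = Vt * cx_vec(q, vec(nint, fill::zeros));  // u for propagator j
      double denom = nrm(j) * dot(q, PK.col(j));
      if (denom > 0.0 && std::isfinite(denom)) {
        cx_vec u = wq / denom;
        const cx_vec& wv = Wv.col(j);
        const cx_vec& ea = Ea.col(j);
        U1.col(col) = u % ea; U2.col(col) = u;
        W1.col(col) = wv;     W2.col(col) = wv % ea;
        ++col;
        double dt = dts(j);
        for (size_t s = 0; s < deg.size(); ++s) {
          int a = deg[s].first, b = deg[s].second;
          cx_double lim = (a == b) ? (-dt * ea(a))
            : (-dt * std::exp(-0.5 * (mu(a) + mu(b)) * dt));
          Mdeg(a, b) += u(a) * wv(b) * lim;
        }
      }
      cx_vec back = Vinvt * (wq % Ea.col(j));
      if (j > 0) {
        // gradient of emission factor j-1 (neuron ids(j-1))
        int i = ids(j - 1);
        vec qlam = real(back);               // adjoint after Lambda_{j-1}
        double sc = norm(qlam, 1);
        if (sc > 0) qlam /= sc;
        const vec pk = PK.col(j - 1);        // state entering Lambda_{j-1}
        double ed = dot(qlam, fint.col(i) % pk);
        if (ed > 0.0 && std::isfinite(ed)) demis.col(i) += (qlam % pk) / ed;
        q = qlam % fint.col(i);              // adjoint after propagator j-1
        double sc2 = norm(q, 1);
        if (sc2 > 0) q /= sc2;
      } else {
        vec q0 = real(back);                 // adjoint covering all but p0
        double d0 = dot(q0, p0int);
        if (d0 > 0.0 && std::isfinite(d0)) dp0 += q0 / d0;
      }
    }
  }

  cx_mat Macc = Mdeg;
  if (col > 0) {
    Macc += (U1.cols(0, col - 1) * W1.cols(0, col - 1).st()
             - U2.cols(0, col - 1) * W2.cols(0, col - 1).st()) % invd;
  }
  mat G = real(Vinvt * Macc * Vt);
  return Rcpp::List::create(Rcpp::Named("loglik") = logl_total,
                            Rcpp::Named("G") = G,
                            Rcpp::Named("demis") = demis,
                            Rcpp::Named("dp0") = dp0,
                            Rcpp::Named("n_ok") = n_ok);
}

// Max-sum Viterbi over grid-valued latent paths at event times.
// log_p0, log_f are log densities/rates at interior nodes; transition kernel
// densities are exp(-H dt) applied to point masses (columns scaled by 1/w).
// Returns the 0-based interior-node index path at {t0, spikes} plus the
// terminal boundary (-1 or +1) and the path log-score.
// [[Rcpp::export]]
Rcpp::List fp_viterbi_cpp(const arma::cx_mat& V, const arma::cx_mat& Vinv,
                          const arma::cx_vec& mu, const arma::vec& wint,
                          const arma::vec& log_p0, const arma::mat& log_f,
                          const arma::vec& aL, const arma::vec& aR,
                          const arma::vec& dts, const arma::ivec& ids) {
  int nint = log_p0.n_elem, N = ids.n_elem;
  const double NEG = -1e300;
  vec score = log_p0;
  imat back(nint, N, fill::zeros);
  cx_mat Vt = V.st();

  // running rescale to avoid overflow is unnecessary in log domain
  for (int j = 0; j < N; ++j) {
    // kernel K(dt): columns = densities from point masses
    cx_mat E = Vinv;
    E.each_col() %= exp(-mu * dts(j));
    mat Kd = real(V * E);                // exp(-H dt)
    vec newscore(nint);
    ivec arg(nint);
    for (int m = 0; m < nint; ++m) {
      double best = NEG;
      int bi = 0;
      for (int n = 0; n < nint; ++n) {
        double kv = Kd(m, n) / wint(n);
        double lt = (kv > 0) ? std::log(kv) : NEG;
        double s = score(n) + lt;
        if (s > best) { best = s; bi = n; }
      }
      newscore(m) = best + log_f(m, ids(j));
      arg(m) = bi;
    }
    score = newscore;
    back.col(j) = arg;
  }
  // terminal: absorption through the final interval
  cx_mat E = Vinv;
  E.each_col() %= exp(-mu * dts(N));
  mat Kd = real(V * E);
  vec gl = Kd.t() * aL, gr = Kd.t() * aR;   // g_b(n) = a_b' K e_n (before /w)
  double bestL = NEG, bestR = NEG;
  int argL = 0, argR = 0;
  for (int n = 0; n < nint; ++n) {
    double vl = gl(n) / wint(n), vr = gr(n) / wint(n);
    double sl = score(n) + (vl > 0 ? std::log(vl) : NEG);
    double sr = score(n) + (vr > 0 ? std::log(vr) : NEG);
    if (sl > bestL) { bestL = sl; argL = n; }
    if (sr > bestR) { bestR = sr; argR = n; }
  }
  int boundary;
  int last;
  if (std::abs(bestL - bestR) < 1e-12) {
    // tie: boundary of the half last visited by the decoded interior path
    last = (bestL >= bestR) ? argL : argR;
    boundary = (last >= nint / 2) ? 1 : -1;
    last = (boundary > 0) ? argR : argL;
  } else if (bestL > bestR) {
    boundary = -1; last = argL;
  } else {
    boundary = 1; last = argR;
  }
  // back.col(j) maps the state index at event j+1 to the argmax state at event j
  ivec path(N + 1);
  path(N) = last;
  for (int j = N - 1; j >= 0; --j) path(j) = back(path(j + 1), j);
  double total = std::max(bestL, bestR);
  return Rcpp::List::create(Rcpp::Named("states") = path,
                            Rcpp::Named("boundary") = boundary,
                            Rcpp::Named("logscore") = total);
}

static double interp_lin(const vec& xs, const vec& ys, double x) {
  if (x <= xs(0)) return ys(0);
  int n = xs.n_elem;
  if (x >= xs(n - 1)) return ys(n - 1);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (xs(mid) <= x) lo = mid; else hi = mid; }
  double t = (x - xs(lo)) / (xs(lo + 1) - xs(lo));
  return ys(lo) * (1 - t) + ys(lo + 1) * t;
}

// Euler-Maruyama simulation of dx = D F(x) dt + sqrt(2 D) dW with first
// passage at +-1 and Poisson spike emission by per-step thinning.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::List sim_langevin_cpp(const arma::vec& nodes, const arma::vec& F,
                            const arma::mat& tuning, double D,
                            const arma::vec& x0s, double dt, double t_max,
                            bool track_f2) {
  int n_trials = x0s.n_elem, M = tuning.n_cols;
  double sq = std::sqrt(2.0 * D * dt);
  Rcpp::List out(n_trials);
  for (int k = 0; k < n_trials; ++k) {
    double x = x0s(k), t = 0.0;
    std::vector<double> st;   // spike times
    std::vector<int> si;      // neuron ids (1-based)
    double f2int = 0.0;
    int boundary = 0;
    bool truncated = false;
    while (true) {
      if (t >= t_max) { truncated = true; break; }
      double Fx = interp_lin(nodes, F, x);
      if (track_f2) f2int += Fx * Fx * dt;
      double xn = x + D * Fx * dt + sq * R::norm_rand();
      double t_end = t + dt;
      bool crossed = false;
      if (xn >= 1.0) {
        double th = (1.0 - x) / (xn - x);
        t_end = t + th * dt;
        boundary = 1; crossed = true;
      } else if (xn <= -1.0) {
        double th = (-1.0 - x) / (xn - x);
        t_end = t + th * dt;
        boundary = -1; crossed = true;
      } else {
        // Brownian-bridge correction: the path may have touched a boundary
        // within the step even though both endpoints are interior; ignoring
        // this biases first-passage times long by O(sqrt(dt)).
        double var2 = 2.0 * D * dt;
        double pR = std::exp(-2.0 * (1.0 - x) * (1.0 - xn) / var2);
        double pL = std::exp(-2.0 * (1.0 + x) * (1.0 + xn) / var2);
        double u = R::unif_rand();
        if (u < pR) {
          boundary = 1; crossed = true;
          t_end = t + 0.5 * dt;
        } else if (u < pR + pL) {
          boundary = -1; crossed = true;
          t_end = t + 0.5 * dt;
        }
      }
      for (int i = 0; i < M; ++i) {
        double rate = interp_lin(nodes, tuning.col(i), x);
        if (rate <= 0) continue;
        if (R::unif_rand() < rate * dt) {
          double ts = t + R::unif_rand() * dt;
          if (ts < t_end && ts > 0) { st.push_back(ts); si.push_back(i + 1); }
        }
      }
      if (crossed) { t = t_end; break; }
      x = xn; t = t_end;
    }
    out[k] = Rcpp::List::create(Rcpp::Named("tE") = t,
                                Rcpp::Named("times") = st,
                                Rcpp::Named("ids") = si,
                                Rcpp::Named("boundary") = boundary,
                                Rcpp::Named("truncated") = truncated,
                                Rcpp::Named("f2int") = f2int);
  }
  return out;
}
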