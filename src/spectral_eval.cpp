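// Core spectral evaluation: Lorentzian linear-combination forward model,
// analytic Jacobian, and a box-constrained Levenberg-Marquardt used for
// per-transient fits. Parameter layout per transient (length P):
//   [ conc (K) | gamma (G) | eps (G) | phi0 | phi1 | b_re (nb) | b_im (nb) ]
// gamma in s^-1, eps in rad s^-1, phi0 in rad, phi1 in s, nu in Hz.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const cx_double J1(0.0, 1.0);

// Iterative radix-2 FFT with a per-size twiddle cache. Armadillo's fft
// re-plans on every call, which dominates the cost of the many small
// transforms the fitting loops need; all acquisition grids in this
// package are powers of two. Falls back to arma::fft otherwise.
static const std::vector<cx_double>& twiddles(unsigned int n) {
  static std::map<unsigned int, std::vector<cx_double>> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  std::vector<cx_double> w(n / 2);
  for (unsigned int k = 0; k < n / 2; ++k) {
    double a = -2.0 * M_PI * k / n;
    w[k] = cx_double(std::cos(a), std::sin(a));
  }
  return cache.emplace(n, std::move(w)).first->second;
}

static cx_vec fft_pow2(const cx_vec& x) {
  const unsigned int n = x.n_elem;
  if (n == 0 || (n & (n - 1)) != 0) return fft(x);
  cx_vec y(n);
  // bit-reversal permutation
  unsigned int j = 0;
  for (unsigned int i = 0; i < n; ++i) {
    y(j) = x(i);
    unsigned int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
  }
  const std::vector<cx_double>& w = twiddles(n);
  for (unsigned int len = 2; len <= n; len <<= 1) {
    unsigned int step = n / len;
    for (unsigned int i = 0; i < n; i += len) {
      for (unsigned int k = 0; k < len / 2; ++k) {
        cx_double u = y(i + k);
        cx_double v = y(i + k + len / 2) * w[k * step];
        y(i + k) = u + v;
        y(i + k + len / 2) = u - v;
      }
    }
  }
  return y;
}

// Evaluate model spectrum (and optionally complex Jacobian) for one
// transient. basis: n x K complex FIDs; sel: 0-based indices into the
// fft output picking the (fftshifted, windowed) bins in ascending-ppm
// order; nu: selected frequency axis (Hz, length nsel); Breg: nsel x nb
// real baseline regressors (may have 0 cols).
static void eval_one(const cx_mat& basis, const uvec& group, const vec& tau,
                     const vec& nu, const uvec& sel, const mat& Breg,
                     const vec& p, unsigned int K, unsigned int G,
                     double sqrtn, bool want_jac,
                     cx_vec& spec, cx_mat& jac) {
  const unsigned int nsel = sel.n_elem;
  const unsigned int nb = Breg.n_cols;
  const unsigned int P = K + 2 * G + 2 + 2 * nb;

  const vec conc = p.subvec(0, K - 1);
  const vec gam = p.subvec(K, K + G - 1);
  const vec eps = p.subvec(K + G, K + 2 * G - 1);
  const double phi0 = p(K + 2 * G);
  const double phi1 = p(K + 2 * G + 1);

  cx_vec phase = exp(cx_vec(vec(nu.n_elem, fill::zeros), -(phi0 + nu * phi1)));

  if (want_jac) jac.set_size(nsel, P);

  // Per-metabolite broadened/shifted spectra; accumulate group FIDs for
  // the gamma/eps gradient.
  cx_vec metab(nsel, fill::zeros);
  std::vector<cx_vec> groupY(G);
  for (unsigned int g = 0; g < G; ++g) groupY[g] = cx_vec(basis.n_rows, fill::zeros);

  std::vector<cx_vec> mods(G);
  for (unsigned int g = 0; g < G; ++g)
    mods[g] = exp(cx_vec(-tau * gam(g), -tau * eps(g)));

  for (unsigned int k = 0; k < K; ++k) {
    const unsigned int g = group(k);
    cx_vec yk = basis.col(k) % mods[g];
    groupY[g] += conc(k) * yk;
    cx_vec Sk_full = fft_pow2(yk) / sqrtn;
    cx_vec Sk = phase % Sk_full.elem(sel);
    metab += conc(k) * Sk;
    if (want_jac) jac.col(k) = Sk;
  }

  spec = metab;
  for (unsigned int b = 0; b < nb; ++b) {
    spec += cx_vec(Breg.col(b) * p(K + 2 * G + 2 + b),
                   Breg.col(b) * p(K + 2 * G + 2 + nb + b));
  }

  if (!want_jac) return;

  for (unsigned int g = 0; g < G; ++g) {
    cx_vec tmp = cx_vec(-tau, vec(tau.n_elem, fill::zeros)) % groupY[g];
    cx_vec dfull = fft_pow2(tmp) / sqrtn;
    cx_vec dgam = phase % dfull.elem(sel);
    jac.col(K + g) = dgam;          // d/d gamma_g
    jac.col(K + G + g) = J1 * dgam; // d/d eps_g
  }
  jac.col(K + 2 * G) = -J1 * metab;                          // d/d phi0
  jac.col(K + 2 * G + 1) = -J1 * (cx_vec(nu, vec(nu.n_elem, fill::zeros)) % metab); // d/d phi1
  for (unsigned int b = 0; b < nb; ++b) {
    jac.col(K + 2 * G + 2 + b) = cx_vec(Breg.col(b), vec(nsel, fill::zeros));
    jac.col(K + 2 * G + 2 + nb + b) = cx_vec(vec(nsel, fill::zeros), Breg.col(b));
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_eval_block(const arma::cx_mat& basis, const arma::uvec& group,
                          const arma::vec& tau, const arma::vec& nu,
                          const arma::uvec& sel, const arma::mat& Breg,
                          const arma::mat& params, bool want_jac,
                          Rcpp::Nullable<Rcpp::List> basis_per_t = R_NilValue) {
  const unsigned int K = basis.n_cols;
  const unsigned int G = group.max() + 1;
  const unsigned int T = params.n_cols;
  const unsigned int nsel = sel.n_elem;
  const double sqrtn = std::sqrt((double)basis.n_rows);

  cx_mat spec(nsel, T);
  cx_cube jac;
  if (want_jac) jac.set_size(nsel, params.n_rows, T);

  bool per_t = basis_per_t.isNotNull();
  Rcpp::List blist;
  if (per_t) blist = Rcpp::List(basis_per_t);

  for (unsigned int t = 0; t < T; ++t) {
    cx_vec s;
    cx_mat J;
    if (per_t) {
      cx_mat bt = Rcpp::as<cx_mat>(blist[t]);
      eval_one(bt, group, tau, nu, sel, Breg, params.col(t), K, G, sqrtn,
               want_jac, s, J);
    } else {
      eval_one(basis, group, tau, nu, sel, Breg, params.col(t), K, G, sqrtn,
               want_jac, s, J);
    }
    spec.col(t) = s;
    if (want_jac) jac.slice(t) = J;
  }
  if (want_jac)
    return Rcpp::List::create(Rcpp::Named("spec") = spec,
                              Rcpp::Named("jac") = jac);
  return Rcpp::List::create(Rcpp::Named("spec") = spec);
}

// Accumulate dynamic-fit normal equations. data: nsel x T observed spectra;
// Mcube: P_spec x P_theta x T chain Jacobians d(spectral params)/d(theta).
// Returns JtJ (P_theta^2), Jtg (P_theta), rss where J stacks re/im residual
// gradients over all transients.
// [[Rcpp::export]]
Rcpp::List cpp_dyn_normal_eqs(const arma::cx_mat& basis, const arma::uvec& group,
                              const arma::vec& tau, const arma::vec& nu,
                              const arma::uvec& sel, const arma::mat& Breg,
                              const arma::mat& params, const arma::cube& Mcube,
                              const arma::cx_mat& data,
                              Rcpp::Nullable<Rcpp::List> basis_per_t = R_NilValue) {
  const unsigned int K = basis.n_cols;
  const unsigned int G = group.max() + 1;
  const unsigned int T = params.n_cols;
  const unsigned int Pth = Mcube.n_cols;
  const double sqrtn = std::sqrt((double)basis.n_rows);

  mat JtJ(Pth, Pth, fill::zeros);
  vec Jtg(Pth, fill::zeros);
  double rss = 0.0;

  bool per_t = basis_per_t.isNotNull();
  Rcpp::List blist;
  if (per_t) blist = Rcpp::List(basis_per_t);

  for (unsigned int t = 0; t < T; ++t) {
    cx_vec s;
    cx_mat J;
    if (per_t) {
      cx_mat bt = Rcpp::as<cx_mat>(blist[t]);
      eval_one(bt, group, tau, nu, sel, Breg, params.col(t), K, G, sqrtn, true,
               s, J);
    } else {
      eval_one(basis, group, tau, nu, sel, Breg, params.col(t), K, G, sqrtn,
               true, s, J);
    }
    cx_vec r = s - data.col(t);
    rss += accu(square(real(r))) + accu(square(imag(r)));
    // accumulate in spectral space, then project through the chain
    // Jacobian M(t): J_theta = J_spec M, so J_theta' J_theta = M' A M
    // with A the real normal matrix of the stacked re/im residuals.
    mat Jr = join_cols(real(J), imag(J));
    vec rr = join_cols(real(r), imag(r));
    mat A = Jr.t() * Jr;
    vec gs = Jr.t() * rr;
    const mat& M = Mcube.slice(t);
    JtJ += M.t() * A * M;
    Jtg += M.t() * gs;
  }
  return Rcpp::List::create(Rcpp::Named("JtJ") = JtJ, Rcpp::Named("Jtg") = Jtg,
                            Rcpp::Named("rss") = rss);
}

// Residual sum of squares only (for LM step acceptance in dynamic fits).
// [[Rcpp::export]]
double cpp_dyn_rss(const arma::cx_mat& basis, const arma::uvec& group,
                   const arma::vec& tau, const arma::vec& nu,
                   const arma::uvec& sel, const arma::mat& Breg,
                   const arma::mat& params, const arma::cx_mat& data,
                   Rcpp::Nullable<Rcpp::List> basis_per_t = R_NilValue) {
  const unsigned int K = basis.n_cols;
  const unsigned int G = group.max() + 1;
  const unsigned int T = params.n_cols;
  const double sqrtn = std::sqrt((double)basis.n_rows);
  double rss = 0.0;
  bool per_t = basis_per_t.isNotNull();
  Rcpp::List blist;
  if (per_t) blist = Rcpp::List(basis_per_t);
  for (unsigned int t = 0; t < T; ++t) {
    cx_vec s;
    cx_mat J;
    if (per_t) {
      cx_mat bt = Rcpp::as<cx_mat>(blist[t]);
      eval_one(bt, group, tau, nu, sel, Breg, params.col(t), K, G, sqrtn,
               false, s, J);
    } else {
      eval_one(basis, group, tau, nu, sel, Breg, params.col(t), K, G, sqrtn,
               false, s, J);
    }
    cx_vec r = s - data.col(t);
    rss += accu(square(real(r))) + accu(square(imag(r)));
  }
  return rss;
}

static vec clamp_box(const vec& p, const vec& lo, const vec& hi) {
  vec out = p;
  for (unsigned int i = 0; i < p.n_elem; ++i) {
    if (out(i) < lo(i)) out(i) = lo(i);
    if (out(i) > hi(i)) out(i) = hi(i);
  }
  return out;
}

// Box-constrained Levenberg-Marquardt for a single transient.
// [[Rcpp::export]]
Rcpp::List cpp_fit_transient(const arma::cx_vec& data, const arma::cx_mat& basis,
                             const arma::uvec& group, const arma::vec& tau,
                             const arma::vec& nu, const arma::uvec& sel,
                             const arma::mat& Breg, const arma::vec& p0,
                             const arma::vec& lower, const arma::vec& upper,
                             int max_iter, double ftol, double gtol) {
  const unsigned int K = basis.n_cols;
  const unsigned int G = group.max() + 1;
  const double sqrtn = std::sqrt((double)basis.n_rows);
  const unsigned int P = p0.n_elem;

  vec p = clamp_box(p0, lower, upper);
  cx_vec s;
  cx_mat Jc;
  eval_one(basis, group, tau, nu, sel, Breg, p, K, G, sqrtn, true, s, Jc);
  cx_vec r = s - data;
  double cost = accu(square(real(r))) + accu(square(imag(r)));

  double lambda = 1e-3;
  bool converged = false;
  int iter = 0;
  mat Jr = join_cols(real(Jc), imag(Jc));
  vec rr = join_cols(real(r), imag(r));
  mat JtJ = Jr.t() * Jr;
  vec g = Jr.t() * rr;

  for (iter = 0; iter < max_iter; ++iter) {
    if (norm(g, "inf") < gtol * (1.0 + cost)) { converged = true; break; }
    vec D = JtJ.diag();
    D.transform([](double v) { return v > 1e-12 ? v : 1e-12; });
    bool accepted = false;
    for (int tries = 0; tries < 50; ++tries) {
      mat A = JtJ;
      A.diag() += lambda * D;
      vec delta;
      bool ok = solve(delta, A, -g, solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) { lambda *= 10.0; continue; }
      vec pn = clamp_box(p + delta, lower, upper);
      cx_vec s2; cx_mat Jc2;
      eval_one(basis, group, tau, nu, sel, Breg, pn, K, G, sqrtn, false, s2, Jc2);
      cx_vec r2 = s2 - data;
      double cost2 = accu(square(real(r2))) + accu(square(imag(r2)));
      if (cost2 < cost) {
        double rel = (cost - cost2) / std::max(cost, 1e-300);
        p = pn;
        eval_one(basis, group, tau, nu, sel, Breg, p, K, G, sqrtn, true, s, Jc);
        r = s - data;
        cost = cost2;
        Jr = join_cols(real(Jc), imag(Jc));
        rr = join_cols(real(r), imag(r));
        JtJ = Jr.t() * Jr;
        g = Jr.t() * rr;
        lambda = std::max(lambda * 0.3, 1e-12);
        accepted = true;
        if (rel < ftol) { converged = true; }
        break;
      }
      lambda *= 10.0;
      if (lambda > 1e14) break;
    }
    if (!accepted) { converged = true; break; } // stalled: local optimum
    if (converged) break;
  }
  return Rcpp::List::create(Rcpp::Named("par") = p, Rcpp::Named("rss") = cost,
                            Rcpp::Named("niter") = iter,
                            Rcpp::Named("converged") = converged);
}

// Fit every transient of a series independently (shared setup, one call).
// [[Rcpp::export]]
Rcpp::List cpp_fit_block(const arma::cx_mat& data, const arma::cx_mat& basis,
                         const arma::uvec& group, const arma::vec& tau,
                         const arma::vec& nu, const arma::uvec& sel,
                         const arma::mat& Breg, const arma::mat& p0,
                         const arma::vec& lower, const arma::vec& upper,
                         int max_iter, double ftol, double gtol) {
  const unsigned int T = data.n_cols;
  mat est(p0.n_rows, T);
  vec rss(T);
  ivec niter(T);
  ivec conv(T);
  for (unsigned int t = 0; t < T; ++t) {
    Rcpp::List res = cpp_fit_transient(data.col(t), basis, group, tau, nu, sel,
                                       Breg, p0.col(t), lower, upper, max_iter,
                                       ftol, gtol);
    est.col(t) = Rcpp::as<vec>(res["par"]);
    rss(t) = Rcpp::as<double>(res["rss"]);
    niter(t) = Rcpp::as<int>(res["niter"]);
    conv(t) = Rcpp::as<bool>(res["converged"]) ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("par") = est, Rcpp::Named("rss") = rss,
                            Rcpp::Named("niter") = niter,
                            Rcpp::Named("converged") = conv);
}
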