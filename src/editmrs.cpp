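// Numerical kernels kept in compiled code: these run inside per-transient and
// per-iteration loops of the cohort study, where call counts reach 1e5-1e6.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson non-negative least squares: min ||A x - b||^2 s.t. x >= 0,
// run on the normal equations (AtA, Atb precomputed once) so active-set
// subproblems are small dense solves. Free-signed coefficients are handled by
// the caller via duplicated +/- columns.
// [[Rcpp::export]]
arma::vec nnls_lh(const arma::mat& A, const arma::vec& b, double tol = -1.0,
                  int maxit = -1) {
  const uword n = A.n_cols;
  if (maxit < 0) maxit = 5 * static_cast<int>(n) + 50;
  mat AtA = A.t() * A;
  vec Atb = A.t() * b;
  if (tol < 0) tol = 10.0 * datum::eps * norm(AtA, 1);
  vec x(n, fill::zeros);
  vec w = Atb;
  std::vector<bool> inP(n, false);
  int outer = 0;
  while (outer++ < maxit) {
    int j = -1; double wmax = tol;
    for (uword k = 0; k < n; ++k)
      if (!inP[k] && w(k) > wmax) { wmax = w(k); j = static_cast<int>(k); }
    if (j < 0) break;
    inP[j] = true;
    for (int inner = 0; inner < maxit; ++inner) {
      uvec P(n); uword np = 0;
      for (uword k = 0; k < n; ++k) if (inP[k]) P(np++) = k;
      P.resize(np);
      vec z;
      if (!solve(z, AtA.submat(P, P), Atb(P), solve_opts::likely_sympd)) {
        inP[j] = false; break;
      }
      bool feasible = true;
      for (uword k = 0; k < np; ++k) if (z(k) <= 0) { feasible = false; break; }
      if (feasible) {
        x.zeros();
        for (uword k = 0; k < np; ++k) x(P(k)) = z(k);
        break;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (uword k = 0; k < np; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      for (uword k = 0; k < np; ++k)
        if (x(P(k)) <= 1e-12) { inP[P(k)] = false; x(P(k)) = 0.0; }
    }
    w = Atb - AtA * x;
  }
  return x;
}

// Pointwise median across transients (columns are transients).
// [[Rcpp::export]]
arma::cx_vec row_median_cx(const arma::cx_mat& S) {
  return cx_vec(median(real(S), 1), median(imag(S), 1));
}

// Registration of one transient to a reference, exact in phase: the squared
// time-domain distance ||s e^{i(2 pi df t + phi)} - ref||^2 is, for fixed df,
// minimized by phi = -Arg z(df) with z(df) = sum_t e^{i 2 pi df t} s conj(ref),
// leaving the 1-D problem of maximizing |z(df)|. A coarse grid over
// init +/- half_hz followed by golden-section refinement solves it.
// [[Rcpp::export]]
arma::vec register_profiled(const arma::cx_vec& q, const arma::vec& t,
                            double init, double half_hz = 6.0,
                            double coarse_hz = 1.0, double tol_hz = 2e-3) {
  const std::complex<double> I(0.0, 1.0);
  auto zmag = [&](double df) {
    std::complex<double> z = accu(q % exp(I * (2.0 * datum::pi * df) * t));
    return std::abs(z);
  };
  double best = init, bestv = zmag(init);
  for (double df = init - half_hz; df <= init + half_hz + 1e-12; df += coarse_hz) {
    double v = zmag(df);
    if (v > bestv) { bestv = v; best = df; }
  }
  const double gr = 0.6180339887498949;
  double a = best - coarse_hz, b = best + coarse_hz;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = zmag(x1), f2 = zmag(x2);
  while (b - a > tol_hz) {
    if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = zmag(x2); }
    else { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = zmag(x1); }
  }
  double df = (f1 > f2) ? x1 : x2;
  // parabolic refinement of the correlation peak
  for (int it = 0; it < 2; ++it) {
    double h = std::max(tol_hz, 1e-6);
    double fm = zmag(df - h), f0 = zmag(df), fp = zmag(df + h);
    double denom = fp - 2.0 * f0 + fm;
    if (denom < 0) {
      double step = -0.5 * h * (fp - fm) / denom;
      if (std::abs(step) < 2.0 * h) df += step;
    }
    tol_hz /= 50.0;
  }
  std::complex<double> z = accu(q % exp(I * (2.0 * datum::pi * df) * t));
  return vec{df, -std::arg(z), std::abs(z)};
}

static double reg_obj(double df, double phi, const cx_vec& s, const cx_vec& ref,
                      const vec& t) {
  const std::complex<double> I(0.0, 1.0);
  cx_vec corr = s % exp(I * (2.0 * datum::pi * df * t + phi));
  return accu(square(abs(corr - ref)));
}

// Nelder-Mead over (df [Hz], phi [rad]) minimizing time-domain squared distance
// of the corrected transient to a reference, over a restricted window.
// [[Rcpp::export]]
arma::vec register_nm(const arma::cx_vec& s, const arma::cx_vec& ref,
                      const arma::vec& t, const arma::vec& init,
                      int maxit = 200, double reltol = 1e-9) {
  mat p(3, 2);   // simplex vertices
  vec y(3);
  p.row(0) = rowvec{init(0), init(1)};
  p.row(1) = rowvec{init(0) + 0.5, init(1)};
  p.row(2) = rowvec{init(0), init(1) + 0.2};
  for (int i = 0; i < 3; ++i) y(i) = reg_obj(p(i, 0), p(i, 1), s, ref, t);
  int neval = 3;
  for (int it = 0; it < maxit; ++it) {
    uvec ord = sort_index(y);
    p = p.rows(ord); y = y(ord);
    if (std::abs(y(2) - y(0)) <= reltol * (std::abs(y(0)) + reltol)) break;
    rowvec cen = (p.row(0) + p.row(1)) / 2.0;
    rowvec xr = cen + (cen - p.row(2));
    double yr = reg_obj(xr(0), xr(1), s, ref, t); ++neval;
    if (yr < y(0)) {
      rowvec xe = cen + 2.0 * (cen - p.row(2));
      double ye = reg_obj(xe(0), xe(1), s, ref, t); ++neval;
      if (ye < yr) { p.row(2) = xe; y(2) = ye; } else { p.row(2) = xr; y(2) = yr; }
    } else if (yr < y(1)) {
      p.row(2) = xr; y(2) = yr;
    } else {
      rowvec xc = cen + 0.5 * (p.row(2) - cen);
      double yc = reg_obj(xc(0), xc(1), s, ref, t); ++neval;
      if (yc < y(2)) { p.row(2) = xc; y(2) = yc; }
      else {
        p.row(1) = p.row(0) + 0.5 * (p.row(1) - p.row(0));
        p.row(2) = p.row(0) + 0.5 * (p.row(2) - p.row(0));
        y(1) = reg_obj(p(1, 0), p(1, 1), s, ref, t);
        y(2) = reg_obj(p(2, 0), p(2, 1), s, ref, t);
        neval += 2;
      }
    }
  }
  uvec ord = sort_index(y);
  return vec{p(ord(0), 0), p(ord(0), 1), y(ord(0)), static_cast<double>(neval)};
}

// Whole registration pass in compiled code: for `iters` rounds, rebuild the
// pointwise-median reference over the window rows, then register every
// transient (phase-slope initial guess, phase-profiled golden search) and
// apply the correction over the full FID. Returns corrected transients and
// cumulative per-transient (df, phi).
// [[Rcpp::export]]
Rcpp::List register_all_cpp(arma::cx_mat S, const arma::vec& t_full,
                            int n_win, int iters = 2, double half_hz = 6.0,
                            int stride = 1) {
  const uword ntr = S.n_cols;
  const std::complex<double> I(0.0, 1.0);
  uvec rows = regspace<uvec>(0, stride, n_win - 1);
  vec tw = t_full(rows);
  const int n_use = static_cast<int>(rows.n_elem);
  vec tot_df(ntr, fill::zeros), tot_ph(ntr, fill::zeros);
  for (int it = 0; it < iters; ++it) {
    cx_mat W = S.rows(rows);
    cx_vec ref(median(real(W), 1), median(imag(W), 1));
    for (uword j = 0; j < ntr; ++j) {
      cx_vec q = W.col(j) % conj(ref);
      // weighted phase-slope guess on the unwrapped phase of ref * conj(s)
      vec wgt = abs(q);
      double init = 0.0;
      double wsum = accu(wgt);
      if (wsum > 0) {
        vec ph(n_use);
        double prev = 0.0, off = 0.0;
        for (int i = 0; i < n_use; ++i) {
          double a = -std::arg(q(i));   // phase to apply to s
          if (i > 0) {
            double d = a - prev;
            off -= 2.0 * datum::pi * std::round(d / (2.0 * datum::pi));
          }
          prev = a;
          ph(i) = a + off;
        }
        double tbar = accu(wgt % tw) / wsum;
        double pbar = accu(wgt % ph) / wsum;
        double den = accu(wgt % square(tw - tbar));
        if (den > 0) init = accu(wgt % (tw - tbar) % (ph - pbar)) / den /
          (2.0 * datum::pi);
      }
      vec r = register_profiled(q, tw, init, half_hz);
      S.col(j) %= exp(I * (2.0 * datum::pi * r(0) * t_full + r(1)));
      tot_df(j) += r(0);
      tot_ph(j) += r(1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("S") = S,
                            Rcpp::Named("df_hz") = tot_df,
                            Rcpp::Named("phase") = tot_ph);
}

// Metabolite design matrix for linear-combination modeling: applies per-basis
// Lorentzian broadening (gamma, 1/s), global Gaussian broadening (sigma_g, 1/s)
// and per-basis frequency shift (delta_hz), transforms to the frequency domain
// with zero-filling to zf points, and returns Re{phasor * spectrum} at the
// fit-range bins `idx` (0-based indices into the raw FFT output ordering).
// [[Rcpp::export]]
arma::mat lcm_design_cpp(const arma::cx_mat& basis, const arma::vec& t, int zf,
                         const arma::vec& gamma, double sigma_g,
                         const arma::vec& delta_hz, const arma::uvec& idx,
                         const arma::cx_vec& phasor) {
  const uword M = basis.n_cols;
  const std::complex<double> I(0.0, 1.0);
  vec gdecay = exp(-square(sigma_g * t));
  mat out(idx.n_elem, M);
  for (uword m = 0; m < M; ++m) {
    cx_vec v = basis.col(m) %
      (gdecay % exp(-gamma(m) * t) % exp(I * (2.0 * datum::pi * delta_hz(m)) * t));
    v(0) *= 0.5;   // first-point halving, matching the data transform
    cx_vec sp = fft(v, zf);
    out.col(m) = real(phasor % sp.elem(idx));
  }
  return out;
}

// Full variable-projection inner step for the LCM fit: builds the modified-
// basis design, appends spline regressors (+/- for a free-signed baseline)
// and soft-constraint penalty rows, solves the non-negative least-squares
// problem, and returns coefficients and residuals in one call.
// [[Rcpp::export]]
Rcpp::List lcm_inner_cpp(const arma::cx_mat& basis, const arma::vec& t, int zf,
                         const arma::vec& gamma, double sigma_g,
                         const arma::vec& delta_hz, const arma::uvec& idx,
                         const arma::cx_vec& phasor, const arma::mat& B,
                         const arma::mat& pen, const arma::vec& y,
                         bool want_design = false) {
  const uword M = basis.n_cols, nfit = idx.n_elem, nb = B.n_cols,
              npen = pen.n_rows;
  mat Dmet = lcm_design_cpp(basis, t, zf, gamma, sigma_g, delta_hz, idx,
                            phasor);
  mat Daug(nfit + npen, M + 2 * nb, fill::zeros);
  Daug.submat(0, 0, nfit - 1, M - 1) = Dmet;
  Daug.submat(0, M, nfit - 1, M + nb - 1) = B;
  Daug.submat(0, M + nb, nfit - 1, M + 2 * nb - 1) = -B;
  if (npen > 0) Daug.rows(nfit, nfit + npen - 1) = pen;
  vec yaug(nfit + npen, fill::zeros);
  yaug.subvec(0, nfit - 1) = y;
  vec x = nnls_lh(Daug, yaug);
  vec resid = Daug * x - yaug;
  if (want_design) {
    return Rcpp::List::create(Rcpp::Named("x") = x,
                              Rcpp::Named("resid") = resid,
                              Rcpp::Named("Dmet") = Dmet);
  }
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("resid") = resid);
}

// Dawson's integral F(x) = exp(-x^2) * int_0^x exp(u^2) du, Rybicki's method.
// Used for the dispersion partner of a Gaussian absorption lineshape.
// [[Rcpp::export]]
arma::vec dawson_cpp(const arma::vec& x) {
  const int NMAX = 10;
  const double H = 0.3;
  static double c[NMAX + 1];
  static bool init = false;
  if (!init) {
    for (int i = 1; i <= NMAX; ++i) {
      double d = (2.0 * i - 1.0) * H;
      c[i] = std::exp(-d * d);
    }
    init = true;
  }
  vec out(x.n_elem);
  for (uword k = 0; k < x.n_elem; ++k) {
    double xi = x(k);
    if (std::abs(xi) < 0.2) {
      double x2 = xi * xi;
      out(k) = xi * (1.0 - (2.0 / 3.0) * x2 * (1.0 - 0.4 * x2 * (1.0 - (2.0 / 7.0) * x2)));
    } else {
      double xx = std::abs(xi);
      int n0 = 2 * static_cast<int>(0.5 * xx / H + 0.5);
      double xp = xx - n0 * H;
      double e1 = std::exp(2.0 * xp * H), e2 = e1 * e1;
      double d1 = n0 + 1.0, d2 = d1 - 2.0, sum = 0.0;
      for (int i = 1; i <= NMAX; ++i, d1 += 2.0, d2 -= 2.0, e1 *= e2)
        sum += c[i] * (e1 / d1 + 1.0 / (d2 * e1));
      out(k) = 0.5641895835477563 * std::exp(-xp * xp) * sum * (xi >= 0 ? 1.0 : -1.0);
    }
  }
  return out;
}
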