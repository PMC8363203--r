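// Per-voxel three-compartment fit of the direction-averaged diffusion
// signal. The box (v_ic, v_iso in [0,1], d_e* >= 0) is mapped to R^3 by
// logit / softplus transforms and the objective is minimised by
// Nelder-Mead with incumbent restarts, which avoids projection artifacts
// at the bounds. d_e* is handled internally in units of 1e-3 mm^2/s so
// all three coordinates are O(1).

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

const double DSCALE = 1e-3;   // internal d_e* unit -> mm^2/s

inline double sigmoid(double t) { return 1.0 / (1.0 + std::exp(-t)); }
inline double logit(double p) { return std::log(p / (1.0 - p)); }
inline double softplus(double t) {
  return t > 30.0 ? t : std::log1p(std::exp(t));
}
inline double softplus_inv(double x) {
  return x > 30.0 ? x : std::log(std::expm1(x));
}

struct Objective {
  const double* sbar;    // normalised direction-averaged signals
  const double* b;       // b-values (s/mm^2)
  int nb;
  double dic, diso;
  mutable long evals;

  // f in transformed coordinates t = (t1, t2, t3)
  double operator()(const double* t) const {
    ++evals;
    double vic = sigmoid(t[0]);
    double viso = sigmoid(t[1]);
    double des = softplus(t[2]) * DSCALE;
    double ss = 0.0;
    for (int i = 0; i < nb; ++i) {
      double bi = b[i];
      double model = (1.0 - viso) *
          (vic * std::exp(-bi * vic * dic) +
           (1.0 - vic) * std::exp(-bi * (1.0 - vic) * des)) +
          viso * std::exp(-bi * diso);
      double r = sbar[i] - model;
      ss += r * r;
    }
    return ss;
  }
};

// one Nelder-Mead descent from x0; returns best point in x0, best f
double nelder_mead(const Objective& f, double* x0, double step,
                   double tol, int maxit, int* iters) {
  const int n = 3;
  double sim[4][3], fv[4];
  for (int j = 0; j < n; ++j) sim[0][j] = x0[j];
  fv[0] = f(sim[0]);
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j < n; ++j) sim[i][j] = x0[j];
    sim[i][i - 1] += step;
    fv[i] = f(sim[i]);
  }
  int it = 0;
  int ord[4] = {0, 1, 2, 3};
  while (it < maxit) {
    // order vertices
    std::sort(ord, ord + 4, [&](int a, int b2) { return fv[a] < fv[b2]; });
    int lo = ord[0], hi = ord[3], nh = ord[2];
    if (std::fabs(fv[hi] - fv[lo]) <= tol * (std::fabs(fv[lo]) + tol))
      break;
    ++it;
    double cen[3];
    for (int j = 0; j < n; ++j)
      cen[j] = (sim[ord[0]][j] + sim[ord[1]][j] + sim[ord[2]][j]) / 3.0;
    double xr[3];
    for (int j = 0; j < n; ++j) xr[j] = cen[j] + (cen[j] - sim[hi][j]);
    double fr = f(xr);
    if (fr < fv[ord[0]]) {
      double xe[3];
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - sim[hi][j]);
      double fe = f(xe);
      if (fe < fr) {
        std::copy(xe, xe + 3, sim[hi]); fv[hi] = fe;
      } else {
        std::copy(xr, xr + 3, sim[hi]); fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      std::copy(xr, xr + 3, sim[hi]); fv[hi] = fr;
    } else {
      // contraction
      double xc[3];
      bool outside = fr < fv[hi];
      if (outside) {
        for (int j = 0; j < n; ++j) xc[j] = cen[j] + 0.5 * (cen[j] - sim[hi][j]);
      } else {
        for (int j = 0; j < n; ++j) xc[j] = cen[j] - 0.5 * (cen[j] - sim[hi][j]);
      }
      double fc = f(xc);
      if (fc < std::min(fr, fv[hi])) {
        std::copy(xc, xc + 3, sim[hi]); fv[hi] = fc;
      } else {
        // shrink toward best
        for (int i = 0; i < 4; ++i) {
          if (i == lo) continue;
          for (int j = 0; j < n; ++j)
            sim[i][j] = sim[lo][j] + 0.5 * (sim[i][j] - sim[lo][j]);
          fv[i] = f(sim[i]);
        }
      }
    }
  }
  std::sort(ord, ord + 4, [&](int a, int b2) { return fv[a] < fv[b2]; });
  for (int j = 0; j < n; ++j) x0[j] = sim[ord[0]][j];
  *iters += it;
  return fv[ord[0]];
}

} // namespace

namespace {

// polish from a starting point in box coordinates; returns best objective
double descend(const Objective& f, double vic, double viso, double des,
               double tol, int maxit, int restarts, double* xbest,
               int* iters) {
  const double eps = 1e-3;   // inset boundary starts into the open box
  double x[3];
  x[0] = logit(std::min(std::max(vic, eps), 1.0 - eps));
  x[1] = logit(std::min(std::max(viso, eps), 1.0 - eps));
  x[2] = softplus_inv(std::max(des / DSCALE, eps));
  double best = nelder_mead(f, x, 1.0, tol, maxit, iters);
  for (int r = 0; r < restarts; ++r) {
    double prev = best;
    best = nelder_mead(f, x, 0.25, tol, maxit, iters);
    if (prev - best <= tol * (std::fabs(best) + tol)) break;
  }
  std::copy(x, x + 3, xbest);
  return best;
}

// Levenberg-Marquardt polish in transformed coordinates with the
// analytic Jacobian. The objective is near-degenerate along the ridge
// v_ic d_ic ~ (1 - v_ic) d_e*, where the simplex collapses prematurely;
// curvature-aware steps keep making progress along the valley floor.
double lm_polish(const Objective& f, double* x, double fbest, int maxit) {
  double lambda = 1e-3;
  double t[3] = {x[0], x[1], x[2]};
  for (int it = 0; it < maxit; ++it) {
    double vic = sigmoid(t[0]), viso = sigmoid(t[1]);
    double desu = softplus(t[2]);             // in DSCALE units
    double des = desu * DSCALE;
    double dv1 = vic * (1.0 - vic);           // dvic/dt1
    double dv2 = viso * (1.0 - viso);         // dviso/dt2
    double dv3 = sigmoid(t[2]) * DSCALE;      // ddes/dt3
    double JtJ[3][3] = {{0}}, Jtr[3] = {0};
    double ss = 0.0;
    for (int i = 0; i < f.nb; ++i) {
      double bi = f.b[i];
      double E1 = std::exp(-bi * vic * f.dic);
      double E2 = std::exp(-bi * (1.0 - vic) * des);
      double E3 = std::exp(-bi * f.diso);
      double inner = vic * E1 + (1.0 - vic) * E2;
      double M = (1.0 - viso) * inner + viso * E3;
      double r = f.sbar[i] - M;
      ss += r * r;
      double dMdvic = (1.0 - viso) *
          (E1 - bi * f.dic * vic * E1 - E2 + bi * des * (1.0 - vic) * E2);
      double dMdviso = E3 - inner;
      double dMddes = -(1.0 - viso) * (1.0 - vic) * (1.0 - vic) * bi * E2;
      double J[3] = {-dMdvic * dv1, -dMdviso * dv2, -dMddes * dv3};
      for (int a = 0; a < 3; ++a) {
        Jtr[a] += J[a] * r;
        for (int b2 = 0; b2 < 3; ++b2) JtJ[a][b2] += J[a] * J[b2];
      }
    }
    // solve (JtJ + lambda diag(JtJ)) step = -Jtr by Cholesky-free 3x3
    double A[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b2 = 0; b2 < 3; ++b2)
        A[a][b2] = JtJ[a][b2] + (a == b2 ? lambda * (JtJ[a][a] + 1e-300) : 0.0);
    // Cramer's rule on columns
    auto det3 = [](const double* c0, const double* c1, const double* c2) {
      return c0[0] * (c1[1] * c2[2] - c1[2] * c2[1]) -
             c1[0] * (c0[1] * c2[2] - c0[2] * c2[1]) +
             c2[0] * (c0[1] * c1[2] - c0[2] * c1[1]);
    };
    double c0[3] = {A[0][0], A[1][0], A[2][0]};
    double c1[3] = {A[0][1], A[1][1], A[2][1]};
    double c2[3] = {A[0][2], A[1][2], A[2][2]};
    double rhs[3] = {-Jtr[0], -Jtr[1], -Jtr[2]};
    double det = det3(c0, c1, c2);
    if (!(std::fabs(det) > 0.0)) break;
    double step[3] = {det3(rhs, c1, c2) / det,
                      det3(c0, rhs, c2) / det,
                      det3(c0, c1, rhs) / det};
    double tn[3] = {t[0] + step[0], t[1] + step[1], t[2] + step[2]};
    double fn = f(tn);
    if (fn < ss) {
      std::copy(tn, tn + 3, t);
      lambda = std::max(lambda * 0.3, 1e-12);
      if (ss - fn < 1e-24) break;
    } else {
      lambda *= 10.0;
      if (lambda > 1e12) break;
    }
  }
  double ft = f(t);
  if (ft < fbest) {
    std::copy(t, t + 3, x);
    return ft;
  }
  return fbest;
}

} // namespace

// Fit one voxel. sbar: normalised signals per nonzero shell; bvals: matching
// b-values. Returns (v_ic, v_iso, d_e_star, objective, n_iter, converged).
// The descent from the standard initial conditions is complemented by a
// descent from the best cell of a coarse grid over the box, because the
// objective has local minima that systematically underestimate the
// fractions; the better of the two minima is returned.
// [[Rcpp::export(name = ".fitCompartmentVoxel")]]
NumericVector fit_compartment_voxel(NumericVector sbar, NumericVector bvals,
                                    double dic, double diso,
                                    double vic0, double viso0, double des0,
                                    double tol, int maxit, int restarts) {
  int nb = sbar.size();
  Objective f{REAL(sbar), REAL(bvals), nb, dic, diso, 0};
  int iters = 0;
  double x[3];
  double best = descend(f, vic0, viso0, des0, tol, maxit, restarts, x,
                        &iters);

  // coarse-grid scan for the dominant basin; always polish from its best
  // cell, since the incumbent may sit in a shallow spurious minimum
  double gvic = 0.5, gviso = 0.5, gdes = 1e-3;
  double gbest = std::numeric_limits<double>::infinity();
  for (int i = 0; i <= 12; ++i) {
    double vic = 0.025 + 0.95 * i / 12.0;
    for (int j = 0; j <= 12; ++j) {
      double viso = 0.025 + 0.95 * j / 12.0;
      for (int k = 0; k <= 16; ++k) {
        double des = 0.2e-3 * k;
        double t[3] = {logit(vic), logit(viso),
                       softplus_inv(std::max(des / DSCALE, 1e-3))};
        double fv = f(t);
        if (fv < gbest) { gbest = fv; gvic = vic; gviso = viso; gdes = des; }
      }
    }
  }
  double x2[3];
  double b2 = descend(f, gvic, gviso, gdes, tol, maxit, restarts, x2,
                      &iters);
  if (b2 < best) { best = b2; std::copy(x2, x2 + 3, x); }
  best = lm_polish(f, x, best, 200);

  // The intracellular and extracellular exponents trade off along
  // v_ic d_ic ~ (1 - v_ic) d_e*, producing twin basins separated by small
  // v_ic offsets; sweep curvature-aware descents along the v_ic axis,
  // keeping the incumbent (v_iso, d_e*) as companions.
  // companions re-inset into the open box so no coordinate stays frozen
  // against its transform's boundary
  const double visoC =
      logit(std::min(std::max(sigmoid(x[1]), 0.05), 0.95));
  const double desC =
      softplus_inv(std::min(std::max(softplus(x[2]), 0.05), 30.0));
  const double desAlt = softplus_inv(1.0);  // 1e-3 mm^2/s companion
  for (int k = 1; k < 40; ++k) {
    for (int c = 0; c < 2; ++c) {
      double x3[3] = {logit(k / 40.0), visoC, c == 0 ? desC : desAlt};
      double b3 = f(x3);
      b3 = lm_polish(f, x3, b3 + 1.0, 100); // force acceptance of own min
      if (b3 < best) { best = b3; std::copy(x3, x3 + 3, x); }
    }
  }
  best = lm_polish(f, x, best, 200);
  NumericVector out(6);
  out[0] = sigmoid(x[0]);
  out[1] = sigmoid(x[1]);
  out[2] = softplus(x[2]) * DSCALE;
  out[3] = best;
  out[4] = iters;
  out[5] = std::isfinite(best) ? 1.0 : 0.0;
  return out;
}

// Batched fit: sbar is nshell x nvox (already normalised by S0).
// Returns 6 x nvox matrix with rows (v_ic, v_iso, d_e_star, objective,
// n_iter, converged).
// [[Rcpp::export(name = ".fitCompartmentBatch")]]
NumericMatrix fit_compartment_batch(NumericMatrix sbar, NumericVector bvals,
                                    double dic, double diso,
                                    double vic0, double viso0, double des0,
                                    double tol, int maxit, int restarts) {
  int nb = sbar.nrow(), nv = sbar.ncol();
  if (bvals.size() != nb) stop("bvals length must match nrow(sbar)");
  NumericMatrix out(6, nv);
  NumericVector col(nb);
  for (int v = 0; v < nv; ++v) {
    bool ok = true;
    for (int i = 0; i < nb; ++i) {
      col[i] = sbar(i, v);
      if (!std::isfinite(col[i])) ok = false;
    }
    if (!ok) {
      for (int k = 0; k < 6; ++k) out(k, v) = NA_REAL;
      continue;
    }
    NumericVector r = fit_compartment_voxel(col, bvals, dic, diso,
                                            vic0, viso0, des0,
                                            tol, maxit, restarts);
    for (int k = 0; k < 6; ++k) out(k, v) = r[k];
  }
  return out;
}
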