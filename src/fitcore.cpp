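// Hot paths of the gene-expression model: the gated environmental input,
// the adaptive group LASSO path (block coordinate descent in groupwise
// orthonormal coordinates, driven by 7x7 sufficient statistics), and the
// nonlinear-parameter grid search (shared across genes of one subsample).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double gate_weight1(double clock, double peak, double depth,
                                  double sharp) {
  double c = std::cos(2.0 * M_PI * (clock - peak) / 24.0);
  return (1.0 - depth) + depth * std::pow((1.0 + c) / 2.0, sharp);
}

// Gated, clipped mean of an environmental trace over [t - lag - window, t - lag).
// env grid must be uniform; returns NA where the window leaves the trace.
// nl = (window, lag, peak, depth, sharp, clip_lo, clip_hi)
// [[Rcpp::export]]
NumericVector cpp_env_input(NumericVector env_t, NumericVector env_clock,
                            NumericVector env_val, NumericVector times,
                            NumericVector nl) {
  const double window = nl[0], lag = nl[1], peak = nl[2], depth = nl[3],
               sharp = nl[4], lo = nl[5], hi = nl[6];
  const int m = env_val.size();
  const double t0 = env_t[0];
  const double dt = (m > 1) ? env_t[1] - env_t[0] : 1.0;
  std::vector<double> cs(m + 1, 0.0);
  for (int j = 0; j < m; ++j) {
    double v = env_val[j];
    if (v < lo) v = lo; else if (v > hi) v = hi;
    cs[j + 1] = cs[j] + gate_weight1(env_clock[j], peak, depth, sharp) * v;
  }
  const int n = times.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double a = times[i] - lag - window;   // inclusive
    const double b = times[i] - lag;            // exclusive
    int jlo = (int)std::ceil((a - t0) / dt - 1e-9);
    int jhi = (int)std::ceil((b - t0) / dt - 1e-9) - 1;
    if (jlo < 0 || jhi >= m || jhi < jlo) {
      out[i] = NA_REAL;
    } else {
      out[i] = (cs[jhi + 1] - cs[jlo]) / (double)(jhi - jlo + 1);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Adaptive group LASSO on 7 columns in 3 groups: {age}, {cos,sin},
// {x, x*age, x*cos, x*sin}. Each group is rotated to orthonormal
// coordinates via the eigen decomposition of its centered Gram block, so
// every block coordinate-descent update is closed-form; the penalty
// applies to the orthonormalized coefficients (standardized group LASSO).
// ---------------------------------------------------------------------------

static const int GRP_OFF[4] = {0, 1, 3, 7};   // column offsets of the 3 groups

struct SuffStats {            // gene-independent part, one per design
  int n;
  int peff;                   // kept orthonormal directions (<= 7)
  int goff[4];                // group offsets in c-space
  arma::mat UtU;              // peff x peff, diagonal blocks = n I
  arma::mat A[3];             // V_g diag(1/S_g): maps gv_g -> Uty_g / sqrt(n)
  arma::uvec cols[3];
  arma::vec xbar;             // column means (length 7)
  arma::mat C;                // centered Gram (7x7)
  bool empty;
};

// X: n x 7 (no intercept). Builds centered Gram and rotations.
static void build_stats(const arma::mat& X, SuffStats& st) {
  const int n = X.n_rows;
  st.n = n;
  st.xbar = arma::mean(X, 0).t();
  st.C = X.t() * X - n * (st.xbar * st.xbar.t());
  st.peff = 0;
  st.empty = false;
  int peff = 0;
  for (int g = 0; g < 3; ++g) {
    st.goff[g] = peff;
    arma::uvec cg = arma::regspace<arma::uvec>(GRP_OFF[g], GRP_OFF[g + 1] - 1);
    st.cols[g] = cg;
    arma::mat Cg = st.C.submat(cg, cg);
    arma::vec D; arma::mat Vg;
    if (!arma::eig_sym(D, Vg, arma::symmatu(Cg))) {
      D.zeros(Cg.n_rows); Vg.eye(Cg.n_rows, Cg.n_rows);
    }
    double dmax = D.empty() ? 0.0 : D.max();
    arma::uvec keep = arma::find(D > std::max(1e-12 * dmax, 1e-12));
    st.A[g] = Vg.cols(keep);
    for (arma::uword k = 0; k < keep.n_elem; ++k)
      st.A[g].col(k) /= std::sqrt(D[keep[k]]);
    peff += keep.n_elem;
  }
  st.goff[3] = peff;
  st.peff = peff;
  if (peff == 0) { st.empty = true; return; }
  st.UtU.set_size(peff, peff);
  for (int g = 0; g < 3; ++g) {
    for (int h = 0; h <= g; ++h) {
      if (st.goff[g + 1] == st.goff[g] || st.goff[h + 1] == st.goff[h]) continue;
      arma::mat blk = (double)n *
        (st.A[g].t() * st.C.submat(st.cols[g], st.cols[h]) * st.A[h]);
      st.UtU.submat(st.goff[g], st.goff[h],
                    st.goff[g + 1] - 1, st.goff[h + 1] - 1) = blk;
      if (h != g)
        st.UtU.submat(st.goff[h], st.goff[g],
                      st.goff[h + 1] - 1, st.goff[g + 1] - 1) = blk.t();
    }
  }
}

struct PathResult {
  double c[7];                // best orthonormal coefficients
  double bic;
  double lambda;
  int df;
};

// BIC-selected adaptive group LASSO path given rotated sufficient stats.
// gv: centered X'y (length 7); yy: centered y'y.
static void run_path(const SuffStats& st, const arma::vec& gv, double yy,
                     const arma::vec& lambdas_in, double pilot_ridge,
                     int nlambda, PathResult& out,
                     arma::vec* bic_path = nullptr,
                     arma::vec* lam_path = nullptr) {
  const int n = st.n, peff = st.peff;
  const double logn = std::log((double)n);
  const double sqn = std::sqrt((double)n);

  double Uty[7];
  for (int g = 0; g < 3; ++g) {
    int k = st.goff[g + 1] - st.goff[g];
    if (!k) continue;
    arma::vec ug = sqn * (st.A[g].t() * gv.elem(st.cols[g]));
    for (int j = 0; j < k; ++j) Uty[st.goff[g] + j] = ug[j];
  }
  arma::vec Utyv(&Uty[0], peff, false, true);

  // Pilot ridge fit -> adaptive group weights.
  arma::vec cpilot = arma::solve(
      st.UtU + pilot_ridge * n * arma::eye(peff, peff), Utyv,
      arma::solve_opts::likely_sympd);
  double wg[3];
  for (int g = 0; g < 3; ++g) {
    double s = 0;
    for (int j = st.goff[g]; j < st.goff[g + 1]; ++j) s += cpilot[j] * cpilot[j];
    wg[g] = 1.0 / std::max(std::sqrt(s), 1e-8);
    if (wg[g] > 1e8) wg[g] = 1e8;
  }

  arma::vec lambdas;
  if (lambdas_in.n_elem == 0) {
    double lmax = 0.0;
    for (int g = 0; g < 3; ++g) {
      double s = 0;
      for (int j = st.goff[g]; j < st.goff[g + 1]; ++j) s += Uty[j] * Uty[j];
      double v = std::sqrt(s) / n / wg[g];
      if (v > lmax) lmax = v;
    }
    if (lmax <= 0) lmax = 1e-3;
    lambdas = arma::exp(arma::linspace(std::log(lmax), std::log(lmax * 1e-4),
                                       nlambda));
  } else {
    lambdas = arma::sort(lambdas_in, "descend");
  }
  if (lam_path) *lam_path = lambdas;
  if (bic_path) bic_path->set_size(lambdas.n_elem);

  const double* UU = st.UtU.memptr();     // column-major, peff x peff
  double c[7] = {0, 0, 0, 0, 0, 0, 0};
  double best_c[7] = {0, 0, 0, 0, 0, 0, 0};
  double best_bic = arma::datum::inf, best_lambda = lambdas[0];
  int best_df = 1;
  const double tol = 1e-8 * std::sqrt(std::max(yy / n, 1e-14));

  auto rss_of = [&](const double* cc) {
    double q = 0, l = 0;
    for (int j = 0; j < peff; ++j) {
      l += cc[j] * Uty[j];
      double s = 0;
      for (int k = 0; k < peff; ++k) s += UU[j + k * peff] * cc[k];
      q += cc[j] * s;
    }
    return std::max(yy - 2.0 * l + q, 1e-12);
  };

  for (arma::uword li = 0; li < lambdas.n_elem; ++li) {
    const double lam = lambdas[li];
    if (lam <= 0) {                        // exact least squares
      arma::vec cls = arma::solve(st.UtU, Utyv, arma::solve_opts::likely_sympd);
      int df = 1 + peff;
      double bic = n * std::log(rss_of(cls.memptr()) / n) + df * logn;
      if (bic_path) (*bic_path)[li] = bic;
      if (bic < best_bic) {
        best_bic = bic; best_lambda = 0.0; best_df = df;
        for (int j = 0; j < peff; ++j) best_c[j] = cls[j];
      }
      continue;
    }
    for (int it = 0; it < 500; ++it) {
      double delta = 0.0;
      for (int g = 0; g < 3; ++g) {
        int j0 = st.goff[g], j1 = st.goff[g + 1];
        if (j0 == j1) continue;
        double z[4]; double zn2 = 0;
        for (int j = j0; j < j1; ++j) {
          double s = 0;
          for (int k = 0; k < peff; ++k) s += UU[j + k * peff] * c[k];
          z[j - j0] = c[j] + (Uty[j] - s) / n;
          zn2 += z[j - j0] * z[j - j0];
        }
        double zn = std::sqrt(zn2);
        double shrink = 1.0 - lam * wg[g] / std::max(zn, 1e-300);
        if (shrink < 0) shrink = 0;
        for (int j = j0; j < j1; ++j) {
          double cn = shrink * z[j - j0];
          double d = std::fabs(cn - c[j]);
          if (d > delta) delta = d;
          c[j] = cn;
        }
      }
      if (delta < tol) break;
    }
    int df = 1;
    for (int g = 0; g < 3; ++g) {
      double s = 0;
      for (int j = st.goff[g]; j < st.goff[g + 1]; ++j) s += c[j] * c[j];
      if (s > 0) df += st.goff[g + 1] - st.goff[g];
    }
    double bic = n * std::log(rss_of(c) / n) + df * logn;
    if (bic_path) (*bic_path)[li] = bic;
    if (bic < best_bic) {
      best_bic = bic; best_lambda = lam; best_df = df;
      for (int j = 0; j < peff; ++j) best_c[j] = c[j];
    }
  }
  out.bic = best_bic; out.lambda = best_lambda; out.df = best_df;
  for (int j = 0; j < 7; ++j) out.c[j] = best_c[j];
}

// Back-transform rotated coefficients to the original columns.
static arma::vec back_transform(const SuffStats& st, const double* c) {
  arma::vec beta(7, arma::fill::zeros);
  for (int g = 0; g < 3; ++g) {
    int k = st.goff[g + 1] - st.goff[g];
    if (!k) continue;
    arma::vec cg(k);
    for (int j = 0; j < k; ++j) cg[j] = c[st.goff[g] + j];
    beta.elem(st.cols[g]) = std::sqrt((double)st.n) * (st.A[g] * cg);
  }
  return beta;
}

// [[Rcpp::export]]
List cpp_agl_fit(const arma::mat& X, const arma::vec& y, const arma::ivec& grp,
                 const arma::vec& lambdas, double pilot_ridge, int nlambda) {
  const int n = X.n_rows;
  const double ybar = arma::mean(y);
  const double yy = arma::dot(y, y) - n * ybar * ybar;

  auto intercept_only = [&]() {
    return List::create(_["beta"] = arma::zeros(7), _["b0"] = ybar,
                        _["bic"] = n * std::log(std::max(yy / n, 1e-14)) +
                                   std::log((double)n),
                        _["lambda"] = NA_REAL, _["df"] = 1,
                        _["bic_path"] = arma::vec(), _["lambda_path"] = arma::vec(),
                        _["degenerate"] = true);
  };
  if (yy / n < 1e-14) return intercept_only();

  SuffStats st;
  build_stats(X, st);
  if (st.empty) return intercept_only();
  arma::vec gv = X.t() * y - n * ybar * st.xbar;

  PathResult pr;
  arma::vec bic_path, lam_path;
  run_path(st, gv, yy, lambdas, pilot_ridge, nlambda, pr, &bic_path, &lam_path);
  arma::vec beta = back_transform(st, pr.c);
  double b0 = ybar - arma::dot(st.xbar, beta);
  return List::create(_["beta"] = beta, _["b0"] = b0, _["bic"] = pr.bic,
                      _["lambda"] = pr.lambda, _["df"] = pr.df,
                      _["bic_path"] = bic_path, _["lambda_path"] = lam_path,
                      _["degenerate"] = false);
}

// Criterion of every gene (columns of Y) at every grid point (columns of
// Xenv hold the precomputed environmental inputs). The per-grid-point
// design statistics are built once and shared across genes.
// [[Rcpp::export]]
arma::mat cpp_grid_search_multi(const arma::mat& Xenv, const arma::vec& age,
                                const arma::vec& cosc, const arma::vec& sinc,
                                const arma::mat& Y, const arma::vec& lambdas,
                                double pilot_ridge, int nlambda) {
  const int n = Y.n_rows, ngene = Y.n_cols, G = Xenv.n_cols;
  arma::mat crit(G, ngene);
  crit.fill(arma::datum::inf);

  arma::rowvec ybar = arma::mean(Y, 0);
  arma::vec yy(ngene);
  for (int j = 0; j < ngene; ++j)
    yy[j] = arma::dot(Y.col(j), Y.col(j)) - n * ybar[j] * ybar[j];
  arma::mat Ffix = arma::join_rows(age, cosc, sinc);   // n x 3
  arma::mat FtY = Ffix.t() * Y;                        // 3 x ngene

  arma::mat X(n, 7);
  X.col(0) = age; X.col(1) = cosc; X.col(2) = sinc;
  arma::mat W(n, 4);
  SuffStats st;
  PathResult pr;
  for (int g = 0; g < G; ++g) {
    arma::vec x = Xenv.col(g);
    if (!x.is_finite()) continue;
    W.col(0) = x;
    W.col(1) = x % age;
    W.col(2) = x % cosc;
    W.col(3) = x % sinc;
    X.cols(3, 6) = W;
    build_stats(X, st);
    if (st.empty) continue;
    arma::mat WtY = W.t() * Y;                         // 4 x ngene
    for (int j = 0; j < ngene; ++j) {
      if (yy[j] / n < 1e-14) continue;
      arma::vec gv(7);
      for (int k = 0; k < 3; ++k) gv[k] = FtY(k, j) - n * ybar[j] * st.xbar[k];
      for (int k = 0; k < 4; ++k) gv[3 + k] = WtY(k, j) - n * ybar[j] * st.xbar[3 + k];
      run_path(st, gv, yy[j], lambdas, pilot_ridge, nlambda, pr);
      crit(g, j) = pr.bic;
    }
  }
  return crit;
}

// Single-gene convenience wrapper used by the R-level optimizer.
// [[Rcpp::export]]
List cpp_grid_search(const arma::mat& Xenv, const arma::vec& age,
                     const arma::vec& cosc, const arma::vec& sinc,
                     const arma::vec& y, const arma::vec& lambdas,
                     double pilot_ridge, int nlambda) {
  arma::mat crit = cpp_grid_search_multi(Xenv, age, cosc, sinc,
                                         arma::mat(y), lambdas,
                                         pilot_ridge, nlambda);
  arma::vec cv = crit.col(0);
  arma::uword best = cv.index_min();
  return List::create(_["criterion"] = cv, _["best"] = (int)best + 1);
}

// ---------------------------------------------------------------------------
// Packed multi-trace environmental input and the Nelder-Mead objective.
// Traces are concatenated (values/clocks) with offsets; trace_idx maps each
// sample to its trace (0-based). One call evaluates the full criterion.
// ---------------------------------------------------------------------------

static void env_input_pack_core(const arma::vec& t0s, double dt,
                                const arma::vec& vals, const arma::vec& clocks,
                                const arma::ivec& offsets,
                                const arma::ivec& trace_idx,
                                const arma::vec& times, const double* nl,
                                arma::vec& out) {
  const double window = nl[0], lag = nl[1], peak = nl[2], depth = nl[3],
               sharp = nl[4], lo = nl[5], hi = nl[6];
  const int m = vals.n_elem;
  const int ntr = t0s.n_elem;
  // The clock sequence of a uniform trace repeats with period 24/dt, so the
  // gate needs evaluating only once per cycle position.
  const double Ld = 24.0 / dt;
  const int L = (std::fabs(Ld - std::round(Ld)) < 1e-9) ? (int)std::round(Ld) : 0;
  std::vector<double> gcache(L > 0 ? L : 0);
  arma::vec cs(m + 1);
  cs[0] = 0.0;
  for (int tr = 0; tr < ntr; ++tr) {
    const int o0 = offsets[tr], o1 = offsets[tr + 1];
    for (int j = o0; j < o1; ++j) {
      double v = vals[j];
      if (v < lo) v = lo; else if (v > hi) v = hi;
      double gw;
      const int jj = j - o0;
      if (L > 0 && jj >= L &&
          std::fabs(clocks[j] - clocks[j - L]) < 1e-9) {
        gw = gcache[jj % L];
      } else {
        gw = gate_weight1(clocks[j], peak, depth, sharp);
        if (L > 0 && jj < L) gcache[jj] = gw;
      }
      cs[j + 1] = cs[j] + gw * v;
    }
  }
  const int n = times.n_elem;
  out.set_size(n);
  for (int i = 0; i < n; ++i) {
    const int tr = trace_idx[i];
    const int o0 = offsets[tr], o1 = offsets[tr + 1];
    const double t0 = t0s[tr];
    const double a = times[i] - lag - window;
    const double b = times[i] - lag;
    int jlo = (int)std::ceil((a - t0) / dt - 1e-9);
    int jhi = (int)std::ceil((b - t0) / dt - 1e-9) - 1;
    if (jlo < 0 || jhi >= o1 - o0 || jhi < jlo) { out[i] = NA_REAL; continue; }
    out[i] = (cs[o0 + jhi + 1] - cs[o0 + jlo]) / (double)(jhi - jlo + 1);
  }
}

// [[Rcpp::export]]
arma::vec cpp_env_input_pack(const arma::vec& t0s, double dt,
                             const arma::vec& vals, const arma::vec& clocks,
                             const arma::ivec& offsets,
                             const arma::ivec& trace_idx,
                             const arma::vec& times, const arma::vec& nl) {
  arma::vec out;
  env_input_pack_core(t0s, dt, vals, clocks, offsets, trace_idx, times,
                      nl.memptr(), out);
  return out;
}

// Criterion (BIC of the adaptive group LASSO fit) at one nonlinear setting;
// returns a large value when the look-back window leaves the trace.
// [[Rcpp::export]]
double cpp_nl_criterion(const arma::vec& t0s, double dt, const arma::vec& vals,
                        const arma::vec& clocks, const arma::ivec& offsets,
                        const arma::ivec& trace_idx, const arma::vec& times,
                        const arma::vec& age, const arma::vec& cosc,
                        const arma::vec& sinc, const arma::vec& y,
                        const arma::vec& nl, const arma::vec& lambdas,
                        double pilot_ridge, int nlambda) {
  arma::vec x;
  env_input_pack_core(t0s, dt, vals, clocks, offsets, trace_idx, times,
                      nl.memptr(), x);
  if (!x.is_finite()) return 1e10;
  const int n = y.n_elem;
  const double ybar = arma::mean(y);
  const double yy = arma::dot(y, y) - n * ybar * ybar;
  if (yy / n < 1e-14) return 1e10;
  arma::mat X(n, 7);
  X.col(0) = age; X.col(1) = cosc; X.col(2) = sinc;
  X.col(3) = x; X.col(4) = x % age; X.col(5) = x % cosc; X.col(6) = x % sinc;
  SuffStats st;
  build_stats(X, st);
  if (st.empty) return 1e10;
  arma::vec gv = X.t() * y - n * ybar * st.xbar;
  PathResult pr;
  run_path(st, gv, yy, lambdas, pilot_ridge, nlambda, pr);
  return pr.bic;
}

// Environmental inputs of every sample (rows) at every nonlinear grid row
// (columns); nlmat is n_grid x 7.
// [[Rcpp::export]]
arma::mat cpp_env_input_grid(const arma::vec& t0s, double dt,
                             const arma::vec& vals, const arma::vec& clocks,
                             const arma::ivec& offsets,
                             const arma::ivec& trace_idx,
                             const arma::vec& times, const arma::mat& nlmat) {
  const int G = nlmat.n_rows, n = times.n_elem;
  arma::mat out(n, G);
  arma::vec x;
  for (int g = 0; g < G; ++g) {
    arma::rowvec r = nlmat.row(g);
    env_input_pack_core(t0s, dt, vals, clocks, offsets, trace_idx, times,
                        r.memptr(), x);
    out.col(g) = x;
  }
  return out;
}
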