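// Permutation engine for the kernel differential co-expression test.
//
// Each permutation reconstructs the null expression matrix
//   Y(b) = fitted + s * e_std[perm, ]
// and re-runs the full estimation pipeline (mean fit, variance fit,
// standardization, cross products, kernels) before computing the trace
// statistics. Re-estimating inside the null is what makes the permutation
// distribution match the observed statistic, whose mean/variance
// coefficients are themselves estimated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double gamma_deviance(const vec& y, const vec& mu) {
  double dev = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double r = (y[i] == 0.0) ? 1.0 : y[i] / mu[i];
    dev += 2.0 * ((y[i] - mu[i]) / mu[i] - std::log(r));
  }
  return dev;
}

// gamma GLM with log link; IRLS working weights are identically one, so
// each update is a least-squares solve with the fixed projector Pv
static void gamma_irls(const vec& y2, const mat& Xv, const mat& Pv,
                       vec& eta, double& dev, int maxit, double tol) {
  double dev_old = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    vec mu = exp(eta);
    vec z = eta + (y2 - mu) / mu;
    vec gam = Pv * z;
    eta = Xv * gam;
    dev = gamma_deviance(y2, exp(eta));
    if (std::isfinite(dev_old) &&
        std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) break;
    dev_old = dev;
  }
}

// double GLM for one gene: alternate inverse-variance-weighted least
// squares for the mean with a gamma log-link fit of squared residuals
static bool dglm_gene(const vec& y, const mat& D, const mat& Xv,
                      const mat& Pv, int maxit, double tol,
                      int irls_maxit, double irls_tol,
                      vec& e, vec& s2) {
  const uword n = y.n_elem;
  vec w = ones<vec>(n);
  vec eta;
  bool have_eta = false;
  double dev = 0.0, dev_old = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    mat Dw = D.each_col() % w;
    vec beta;
    if (!solve(beta, Dw.t() * D, Dw.t() * y, solve_opts::no_approx)) {
      return false;
    }
    e = y - D * beta;
    vec y2 = square(e);
    if (!have_eta) {
      eta.set_size(n);
      eta.fill(std::log(mean(y2)));
      have_eta = true;
    }
    gamma_irls(y2, Xv, Pv, eta, dev, irls_maxit, irls_tol);
    w = exp(-eta);
    if (std::isfinite(dev_old) &&
        std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) break;
    dev_old = dev;
  }
  s2 = exp(eta);
  return true;
}

// [[Rcpp::export(name = ".null_stats_engine")]]
Rcpp::List null_stats_engine(const arma::mat& F, const arma::mat& s,
                             const arma::mat& estd, const arma::mat& Q,
                             const arma::mat& D, const arma::mat& Xv,
                             const arma::mat& Pv, const arma::uvec& grp,
                             int ngroups, int var_mode, const arma::mat& Xc,
                             const arma::mat& KX, const arma::umat& perms,
                             const arma::umat& pairs, double nu,
                             bool gauss_rbf, double proj_tol, bool do_lin,
                             bool do_proj, bool do_gauss, bool do_eigen,
                             const arma::mat& Qx, bool recycle_s,
                             int dglm_maxit, double dglm_tol,
                             int irls_maxit, double irls_tol) {
  const uword n = estd.n_rows, r = estd.n_cols;
  const uword q = pairs.n_rows, B = perms.n_cols;
  const int nstat = int(do_lin) + int(do_proj) + int(do_gauss) + int(do_eigen);
  mat stats(B, nstat);
  stats.fill(datum::nan);
  std::vector<int> failed;

  std::vector<std::vector<uword> > gidx(std::max(ngroups, 1));
  if (var_mode == 1) {
    for (uword j = 0; j < n; ++j) gidx[grp[j]].push_back(j);
  }

  for (uword b = 0; b < B; ++b) {
    const uvec perm = perms.col(b);
    mat Yb = F + s % estd.rows(perm);
    mat e, s2b;
    bool ok = true;

    if (var_mode == 2 && !recycle_s) {
      e.set_size(n, r);
      s2b.set_size(n, r);
      for (uword k = 0; k < r && ok; ++k) {
        vec ek, s2k;
        ok = dglm_gene(Yb.col(k), D, Xv, Pv, dglm_maxit, dglm_tol,
                       irls_maxit, irls_tol, ek, s2k);
        if (ok) {
          e.col(k) = ek;
          s2b.col(k) = s2k;
        }
      }
    } else {
      e = Yb - Q * (Q.t() * Yb);
      if (recycle_s) {
        s2b = square(s);
      } else if (var_mode == 1) {
        s2b.set_size(n, r);
        for (int g = 0; g < ngroups && ok; ++g) {
          const std::vector<uword>& id = gidx[g];
          const double ng = double(id.size());
          for (uword k = 0; k < r; ++k) {
            double m = 0.0;
            for (size_t t = 0; t < id.size(); ++t) m += e(id[t], k);
            m /= ng;
            double v = 0.0;
            for (size_t t = 0; t < id.size(); ++t) {
              const double d = e(id[t], k) - m;
              v += d * d;
            }
            v /= (ng - 1.0);
            if (v <= 0.0) { ok = false; break; }
            for (size_t t = 0; t < id.size(); ++t) s2b(id[t], k) = v;
          }
        }
      } else {
        s2b.set_size(n, r);
        const rowvec m = mean(e, 0);
        for (uword k = 0; k < r; ++k) {
          double v = 0.0;
          for (uword j = 0; j < n; ++j) {
            const double d = e(j, k) - m[k];
            v += d * d;
          }
          v /= double(n - 1);
          if (v <= 0.0) { ok = false; break; }
          s2b.col(k).fill(v);
        }
      }
    }
    if (!ok) { failed.push_back(int(b) + 1); continue; }

    mat eb = e / sqrt(s2b);
    mat Z(n, q);
    for (uword i = 0; i < q; ++i) {
      Z.col(i) = eb.col(pairs(i, 0)) % eb.col(pairs(i, 1));
    }
    Z.each_row() -= mean(Z, 0);

    int c = 0;
    if (do_lin) stats(b, c++) = accu(square(Xc.t() * Z)) / double(n);
    mat U;
    vec sv;
    if (do_proj || do_eigen) {
      mat V;
      if (!svd_econ(U, sv, V, Z, "left")) {
        failed.push_back(int(b) + 1);
        continue;
      }
    }
    if (do_proj) {
      if (sv(0) <= 0.0) { failed.push_back(int(b) + 1); continue; }
      uword keep = 0;
      while (keep < sv.n_elem && sv(keep) > proj_tol * sv(0)) ++keep;
      stats(b, c++) = accu(square(U.cols(0, keep - 1).t() * Xc)) / double(n);
    }
    if (do_gauss) {
      mat G = Z * Z.t();
      // exploit symmetry: sum the upper triangle once
      double acc = 0.0;
      if (gauss_rbf) {
        const vec gd = G.diag();
        for (uword jj = 0; jj < n; ++jj) {
          acc += KX(jj, jj);  // exp(0) on the diagonal
          for (uword ii = 0; ii < jj; ++ii) {
            double d2 = gd(ii) + gd(jj) - 2.0 * G(ii, jj);
            if (d2 < 0.0) d2 = 0.0;
            acc += 2.0 * KX(ii, jj) * std::exp(-nu * d2);
          }
        }
      } else {
        for (uword jj = 0; jj < n; ++jj) {
          const double gdd = G(jj, jj);
          acc += KX(jj, jj) * std::exp(-nu * gdd * gdd);
          for (uword ii = 0; ii < jj; ++ii) {
            const double g = G(ii, jj);
            acc += 2.0 * KX(ii, jj) * std::exp(-nu * g * g);
          }
        }
      }
      stats(b, c++) = acc / double(n);
    }
    if (do_eigen) {
      vec u1 = U.col(0);
      u1 -= mean(u1);
      const double tss = dot(u1, u1);
      const double ess = accu(square(Qx.t() * u1));
      stats(b, c++) = (tss > 0.0) ? double(n) * ess / tss : 0.0;
    }
  }

  return Rcpp::List::create(Rcpp::Named("stats") = stats,
                            Rcpp::Named("failed") = failed);
}
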