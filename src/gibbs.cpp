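// Gibbs sampler for Bayesian linear mixed models with unstructured
// covariance random terms (optionally linked to a pedigree relationship
// matrix via its sparse inverse) and heterogeneous residual variances.
// Gaussian and binary-liability (threshold) responses.
//
// Sampling scheme (all conditionals exact; stationary distribution is the
// joint posterior):
//   - fixed effects: one dense multivariate-normal block
//   - each random-term group: level-wise blocks; terms sharing a grouping
//     factor (e.g. additive + permanent environment) are updated jointly
//     per level, conditioning on the other levels through the sparse
//     relationship-matrix inverse (Gauss-Seidel over relatives)
//   - unstructured q x q covariances: inverse-Wishart conditionals
//   - residual variances: per-block inverse-gamma conditionals
//   - threshold family: truncated-normal liability updates, residual
//     variance fixed at 1 on the liability scale
//
// All randomness is deterministic under R's set.seed(): scalar draws with
// conjugate shapes (Wishart chi-squares, residual gammas) use R's RNG
// directly, while the bulk location-effect and liability draws use a fast
// xoshiro256++ stream seeded once from R's RNG (ziggurat normals) -- the
// millions of per-level normal draws dominate the sampler's runtime.

#include <RcppArmadillo.h>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Additive relationship matrix, tabular method. sire/dam are 0-based indices
// into the (topologically sorted) pedigree, or -1 when unknown.
// [[Rcpp::export(name = ".amatrix_cpp")]]
arma::mat amatrix_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s >= i || d >= i)
      stop("pedigree not sorted: parent after offspring at row %d", i + 1);
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += A(j, s);
      if (d >= 0) v += A(j, d);
      v *= 0.5;
      if (v != 0.0) { A(i, j) = v; A(j, i) = v; }
    }
  }
  return A;
}

// ---------------------------------------------------------------------------

namespace {

// xoshiro256++, seeded from R's RNG so everything follows set.seed()
struct FastRng {
  uint64_t s[4];
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }
};

// Marsaglia-Tsang ziggurat standard normals on the fast stream
struct Zig {
  double wn[128], fn[128];
  uint32_t kn[128];
  void init() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1); kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double rnorm(FastRng& rng) {
    for (;;) {
      const int32_t hz = (int32_t)(uint32_t)rng.next();
      const uint32_t iz = (uint32_t)hz & 127u;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      if (iz == 0) {
        double x, y;
        do {
          x = -std::log(rng.runif()) / 3.442619855899;
          y = -std::log(rng.runif());
        } while (y + y < x * x);
        return hz > 0 ? 3.442619855899 + x : -(3.442619855899 + x);
      }
      const double x = hz * wn[iz];
      if (fn[iz] + rng.runif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x)) return x;
    }
  }
};

struct Term {
  arma::ivec level;          // 0-based level per observation
  arma::mat Zt;              // q x n design values (transposed: contiguous per obs)
  int q = 1;
  int nlev = 0;
  int dfn = 0;               // levels counting toward the Wishart df
  bool has_ainv = false;
  arma::ivec Ap, Ai;         // CSC structure of symmetric A-inverse
  arma::vec Ax;
  arma::mat V;               // prior scale
  double nu = 0.002;         // prior degrees of freedom
  arma::mat Ut;              // q x nlev current effects (transposed)
  arma::mat Sigma, Sigmainv; // q x q
};

// Sigma ~ IW(df, Psi): density prop. to |S|^-(df+q+1)/2 exp(-tr(Psi S^-1)/2)
arma::mat riwish(double df, const arma::mat& Psi) {
  const int q = Psi.n_rows;
  arma::mat Ls = arma::chol(arma::inv_sympd(arma::symmatu(Psi)), "lower");
  arma::mat B(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    B(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) B(i, j) = norm_rand();
  }
  arma::mat LW = Ls * B;  // W = LW LW' ~ Wishart(df, Psi^-1)
  arma::mat LWinv = arma::inv(arma::trimatl(LW));
  return arma::symmatu(LWinv.t() * LWinv);
}

// small-matrix Cholesky and triangular solves with plain loops: the group
// updates run thousands of q <= ~8 factorizations per iteration and LAPACK
// call overhead dominates there
inline void chol_small(arma::mat& M, int q, double* rinv) {
  for (int j = 0; j < q; ++j) {
    double d = M(j, j);
    for (int k = 0; k < j; ++k) d -= M(j, k) * M(j, k);
    if (d <= 0.0) stop("conditional precision not positive definite");
    const double lj = std::sqrt(d);
    M(j, j) = lj;
    rinv[j] = 1.0 / lj;
    for (int i = j + 1; i < q; ++i) {
      double v = M(i, j);
      for (int k = 0; k < j; ++k) v -= M(i, k) * M(j, k);
      M(i, j) = v * rinv[j];
    }
  }
}

inline void solve_lower_small(const arma::mat& L, int q, double* x,
                              const double* rinv) {
  for (int i = 0; i < q; ++i) {
    double v = x[i];
    for (int k = 0; k < i; ++k) v -= L(i, k) * x[k];
    x[i] = v * rinv[i];
  }
}

inline void solve_upperT_small(const arma::mat& L, int q, double* x,
                               const double* rinv) {
  for (int i = q - 1; i >= 0; --i) {
    double v = x[i];
    for (int k = i + 1; k < q; ++k) v -= L(k, i) * x[k];
    x[i] = v * rinv[i];
  }
}

} // namespace

// [[Rcpp::export(name = ".gibbs_cpp")]]
List gibbs_cpp(const arma::vec& y_in,
               const arma::mat& X,
               List terms_in,
               List groups_in,
               const arma::ivec& rblock,
               int nrblock,
               double rshape, double rrate,
               int family,          // 0 gaussian, 1 threshold
               const arma::ivec& y01,
               int nitt, int burnin, int thin) {
  const int n = y_in.n_elem;
  const int p = X.n_cols;
  const int nterms = terms_in.size();

  // --- unpack terms -------------------------------------------------------
  std::vector<Term> terms(nterms);
  for (int t = 0; t < nterms; ++t) {
    List tl = terms_in[t];
    Term& tm = terms[t];
    tm.level = as<arma::ivec>(tl["level"]);
    tm.Zt = arma::trans(as<arma::mat>(tl["Z"]));
    tm.q = tm.Zt.n_rows;
    tm.nlev = as<int>(tl["nlev"]);
    if (tm.q > 8) stop("random-term designs with more than 8 columns are not supported");
    tm.V = as<arma::mat>(tl["V"]);
    tm.nu = as<double>(tl["nu"]);
    if (tl.containsElementNamed("Ap") && !Rf_isNull(tl["Ap"])) {
      tm.has_ainv = true;
      tm.Ap = as<arma::ivec>(tl["Ap"]);
      tm.Ai = as<arma::ivec>(tl["Ai"]);
      tm.Ax = as<arma::vec>(tl["Ax"]);
    }
    tm.dfn = tm.nlev;
    tm.Ut.zeros(tm.q, tm.nlev);
    tm.Sigma = tm.V;
    tm.Sigmainv = arma::inv_sympd(arma::symmatu(tm.Sigma));
  }

  // --- groups: indices of terms updated jointly per level ----------------
  // At levels without observations, terms not linked to the relationship
  // matrix have independent N(0, Sigma) effects with no likelihood: they are
  // integrated out exactly (never sampled; excluded from the Wishart degrees
  // of freedom), and only the pedigree-linked blocks are updated there.
  const int ngroups = groups_in.size();
  std::vector<std::vector<int>> groups(ngroups);
  std::vector<std::vector<int>> groups_ainv(ngroups);
  std::vector<std::vector<int>> gobs(ngroups);   // obs sorted by level
  std::vector<std::vector<int>> goff(ngroups);   // level offsets
  std::vector<int> gq(ngroups), gq_ainv(ngroups);
  std::vector<bool> twin(ngroups, false);
  for (int g = 0; g < ngroups; ++g) {
    IntegerVector gi = groups_in[g];
    int qt = 0, qta = 0;
    for (int k = 0; k < gi.size(); ++k) {
      const int t = gi[k] - 1;
      groups[g].push_back(t);
      qt += terms[t].q;
      if (terms[t].has_ainv) {
        groups_ainv[g].push_back(t);
        qta += terms[t].q;
      }
    }
    gq[g] = qt;
    gq_ainv[g] = qta;
    const Term& t0 = terms[groups[g][0]];
    const int nlev = t0.nlev;
    std::vector<int> cnt(nlev + 1, 0);
    for (int o = 0; o < n; ++o) cnt[t0.level[o] + 1]++;
    for (int l = 0; l < nlev; ++l) cnt[l + 1] += cnt[l];
    goff[g] = cnt;
    gobs[g].resize(n);
    std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    for (int o = 0; o < n; ++o) gobs[g][pos[t0.level[o]]++] = o;
    // twin groups (e.g. additive + permanent environment on the same
    // individual design) share one design row per observation, so the
    // likelihood block is a single q x q matrix repeated across quadrants
    twin[g] = false;
    if (gi.size() == 2) {
      const Term& ta = terms[groups[g][0]];
      const Term& tb = terms[groups[g][1]];
      if (ta.q == tb.q &&
          arma::approx_equal(ta.Zt, tb.Zt, "absdiff", 0.0)) twin[g] = true;
    }
    // degrees-of-freedom count for non-pedigree terms: observed levels only
    int nobs_lev = 0;
    for (int l = 0; l < nlev; ++l) if (cnt[l + 1] > cnt[l]) ++nobs_lev;
    for (int k = 0; k < gi.size(); ++k) {
      Term& tm = terms[gi[k] - 1];
      tm.dfn = tm.has_ainv ? tm.nlev : nobs_lev;
    }
  }

  // --- residual bookkeeping ----------------------------------------------
  arma::vec s2(nrblock, arma::fill::ones);
  arma::vec rcount(nrblock, arma::fill::zeros);
  for (int o = 0; o < n; ++o) rcount[rblock[o]] += 1.0;
  if (family == 0) {
    double vy = arma::var(y_in);
    s2.fill(vy > 0 ? vy : 1.0);
  }

  // precomputed X'X per residual block (Rinv changes with s2 only)
  arma::cube XtX(p, p, nrblock, arma::fill::zeros);
  if (p > 0) {
    for (int o = 0; o < n; ++o) {
      const int c = rblock[o];
      for (int a = 0; a < p; ++a) {
        const double xa = X(o, a);
        if (xa == 0.0) continue;
        for (int b2 = 0; b2 <= a; ++b2) XtX(a, b2, c) += xa * X(o, b2);
      }
    }
    for (int c = 0; c < nrblock; ++c)
      XtX.slice(c) = arma::symmatl(XtX.slice(c));
  }

  // --- fast RNG, seeded deterministically from R's stream -----------------
  FastRng rng;
  rng.seed_from_R();
  Zig zig;
  zig.init();

  // --- state ---------------------------------------------------------------
  arma::vec yl = y_in;            // gaussian response or current liability
  arma::vec b(p, arma::fill::zeros);
  arma::vec r = yl;               // residual y - Xb - sum Zu

  // --- output layout -------------------------------------------------------
  int npar = p;
  for (int t = 0; t < nterms; ++t) npar += terms[t].q * (terms[t].q + 1) / 2;
  npar += nrblock;
  const int nsave = (nitt > burnin) ? ((nitt - burnin - 1) / thin + 1) : 0;
  arma::mat out(nsave, npar);
  arma::vec fitted_mean(n, arma::fill::zeros);
  std::vector<arma::mat> u_mean(nterms);
  for (int t = 0; t < nterms; ++t)
    u_mean[t].zeros(terms[t].q, terms[t].nlev);

  arma::vec s2inv(nrblock);
  int isave = 0;

  for (int it = 0; it < nitt; ++it) {
    for (int c = 0; c < nrblock; ++c) s2inv[c] = 1.0 / s2[c];

    // -- threshold: update latent liabilities ------------------------------
    if (family == 1) {
      for (int o = 0; o < n; ++o) {
        const double mu = yl[o] - r[o];
        const bool pos = y01[o] == 1;
        double z = 0.0;
        bool done = false;
        // exact rejection from N(0,1); efficient unless the constraint is
        // far in the tail, where the tail-stable inverse CDF takes over
        for (int trial = 0; trial < 16; ++trial) {
          const double cand = zig.rnorm(rng);
          if (pos ? (mu + cand > 0.0) : (mu + cand < 0.0)) {
            z = cand; done = true; break;
          }
        }
        if (!done) {
          const double u = rng.runif();
          if (pos) {
            const double lp = R::pnorm(-mu, 0.0, 1.0, 0, 1);
            z = R::qnorm(std::log(u) + lp, 0.0, 1.0, 0, 1);
          } else {
            const double lp = R::pnorm(mu, 0.0, 1.0, 0, 1);
            z = -R::qnorm(std::log(u) + lp, 0.0, 1.0, 0, 1);
          }
        }
        const double lnew = mu + z;
        r[o] += lnew - yl[o];
        yl[o] = lnew;
      }
    }

    // -- fixed-effect block -------------------------------------------------
    if (p > 0) {
      arma::vec radd = r + X * b;
      arma::mat M(p, p, arma::fill::zeros);
      for (int c = 0; c < nrblock; ++c) M += XtX.slice(c) * s2inv[c];
      arma::vec w(n);
      for (int o = 0; o < n; ++o) w[o] = radd[o] * s2inv[rblock[o]];
      arma::vec m = X.t() * w;
      arma::mat L = arma::chol(M, "lower");
      arma::vec mu = arma::solve(arma::trimatl(L), m);
      mu = arma::solve(arma::trimatu(L.t()), mu);
      arma::vec z(p);
      for (int a = 0; a < p; ++a) z[a] = zig.rnorm(rng);
      b = mu + arma::solve(arma::trimatu(L.t()), z);
      r = radd - X * b;
    }

    // -- random-term groups --------------------------------------------------
    for (int g = 0; g < ngroups; ++g) {
      const int qt_full = gq[g];
      const int qh = terms[groups[g][0]].q;  // per-term q for twin groups
      arma::mat M(qt_full, qt_full), Wb(qh, qh);
      arma::vec m(qt_full), wv(qt_full), z(qt_full), vb(qh);
      const Term& t0 = terms[groups[g][0]];
      for (int l = 0; l < t0.nlev; ++l) {
        const int k0 = goff[g][l], k1 = goff[g][l + 1];
        const bool observed = k1 > k0;
        const std::vector<int>& gt = observed ? groups[g] : groups_ainv[g];
        const int qt = observed ? qt_full : gq_ainv[g];
        if (qt == 0) continue;
        // add back current contribution of this level
        for (int k = k0; k < k1; ++k) {
          const int o = gobs[g][k];
          double add = 0.0;
          for (size_t ti = 0; ti < gt.size(); ++ti) {
            const Term& tm = terms[gt[ti]];
            for (int j = 0; j < tm.q; ++j) add += tm.Zt(j, o) * tm.Ut(j, l);
          }
          r[o] += add;
        }
        M.zeros(); m.zeros();
        // priors (pedigree-linked terms condition on relatives)
        int ot = 0;
        for (size_t ti = 0; ti < gt.size(); ++ti) {
          const Term& tm = terms[gt[ti]];
          if (tm.has_ainv) {
            double all = 0.0;
            double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
            for (int idx = tm.Ap[l]; idx < tm.Ap[l + 1]; ++idx) {
              const int i2 = tm.Ai[idx];
              const double v = tm.Ax[idx];
              if (i2 == l) all = v;
              else for (int j = 0; j < tm.q; ++j) acc[j] += v * tm.Ut(j, i2);
            }
            for (int j = 0; j < tm.q; ++j) {
              double mv = 0.0;
              for (int k = 0; k < tm.q; ++k) {
                M(ot + j, ot + k) += all * tm.Sigmainv(j, k);
                mv += tm.Sigmainv(j, k) * acc[k];
              }
              m[ot + j] -= mv;
            }
          } else {
            for (int j = 0; j < tm.q; ++j)
              for (int k = 0; k < tm.q; ++k)
                M(ot + j, ot + k) += tm.Sigmainv(j, k);
          }
          ot += tm.q;
        }
        // likelihood contributions
        if (observed && twin[g]) {
          // shared design row: accumulate one q x q block and replicate
          const Term& ta = terms[gt[0]];
          Wb.zeros(); vb.zeros();
          for (int k = k0; k < k1; ++k) {
            const int o = gobs[g][k];
            const double s2i = s2inv[rblock[o]];
            const double rs = r[o] * s2i;
            for (int a = 0; a < qh; ++a) {
              const double za = ta.Zt(a, o);
              if (za == 0.0) continue;
              vb[a] += za * rs;
              const double zas = za * s2i;
              for (int b2 = 0; b2 <= a; ++b2) Wb(a, b2) += zas * ta.Zt(b2, o);
            }
          }
          for (int a = 0; a < qh; ++a) {
            m[a] += vb[a];
            m[qh + a] += vb[a];
            for (int b2 = 0; b2 <= a; ++b2) {
              M(a, b2) += Wb(a, b2);
              M(qh + a, qh + b2) += Wb(a, b2);
            }
            for (int b2 = 0; b2 < qh; ++b2) {
              M(qh + a, b2) += (a >= b2) ? Wb(a, b2) : Wb(b2, a);
            }
          }
        } else {
          for (int k = k0; k < k1; ++k) {
            const int o = gobs[g][k];
            const double s2i = s2inv[rblock[o]];
            ot = 0;
            for (size_t ti = 0; ti < gt.size(); ++ti) {
              const Term& tm = terms[gt[ti]];
              for (int j = 0; j < tm.q; ++j) wv[ot + j] = tm.Zt(j, o);
              ot += tm.q;
            }
            const double rs = r[o] * s2i;
            for (int a = 0; a < qt; ++a) {
              const double was = wv[a] * s2i;
              m[a] += wv[a] * rs;
              for (int b2 = 0; b2 <= a; ++b2) M(a, b2) += was * wv[b2];
            }
          }
        }
        double rinv[16];
        chol_small(M, qt, rinv);            // lower triangle of M -> L
        solve_lower_small(M, qt, m.memptr(), rinv);
        solve_upperT_small(M, qt, m.memptr(), rinv);   // m is now the mean
        for (int a = 0; a < qt; ++a) z[a] = zig.rnorm(rng);
        solve_upperT_small(M, qt, z.memptr(), rinv);
        ot = 0;
        for (size_t ti = 0; ti < gt.size(); ++ti) {
          Term& tm = terms[gt[ti]];
          for (int j = 0; j < tm.q; ++j) tm.Ut(j, l) = m[ot + j] + z[ot + j];
          ot += tm.q;
        }
        for (int k = k0; k < k1; ++k) {
          const int o = gobs[g][k];
          double sub = 0.0;
          for (size_t ti = 0; ti < gt.size(); ++ti) {
            const Term& tm = terms[gt[ti]];
            for (int j = 0; j < tm.q; ++j) sub += tm.Zt(j, o) * tm.Ut(j, l);
          }
          r[o] -= sub;
        }
      }
    }

    // -- covariance updates ---------------------------------------------------
    for (int t = 0; t < nterms; ++t) {
      Term& tm = terms[t];
      arma::mat S(tm.q, tm.q, arma::fill::zeros);
      if (tm.has_ainv) {
        for (int j = 0; j < tm.nlev; ++j) {
          for (int idx = tm.Ap[j]; idx < tm.Ap[j + 1]; ++idx) {
            const int i2 = tm.Ai[idx];
            const double v = tm.Ax[idx];
            for (int a = 0; a < tm.q; ++a)
              for (int b2 = 0; b2 < tm.q; ++b2)
                S(a, b2) += v * tm.Ut(a, i2) * tm.Ut(b2, j);
          }
        }
      } else {
        S = tm.Ut * tm.Ut.t();
      }
      arma::mat Psi = tm.nu * tm.V + S;
      tm.Sigma = riwish(tm.nu + tm.dfn, Psi);
      tm.Sigmainv = arma::inv_sympd(arma::symmatu(tm.Sigma));
    }

    // -- residual variances ---------------------------------------------------
    if (family == 0) {
      arma::vec sse(nrblock, arma::fill::zeros);
      for (int o = 0; o < n; ++o) sse[rblock[o]] += r[o] * r[o];
      for (int c = 0; c < nrblock; ++c)
        s2[c] = (rrate + 0.5 * sse[c]) / R::rgamma(rshape + 0.5 * rcount[c], 1.0);
    }

    // -- record ---------------------------------------------------------------
    if (it >= burnin && (it - burnin) % thin == 0) {
      int col = 0;
      for (int a = 0; a < p; ++a) out(isave, col++) = b[a];
      for (int t = 0; t < nterms; ++t)
        for (int j = 0; j < terms[t].q; ++j)
          for (int i2 = j; i2 < terms[t].q; ++i2)
            out(isave, col++) = terms[t].Sigma(i2, j);
      for (int c = 0; c < nrblock; ++c) out(isave, col++) = s2[c];
      fitted_mean += (yl - r);
      for (int t = 0; t < nterms; ++t) u_mean[t] += terms[t].Ut;
      ++isave;
    }
  }

  if (nsave > 0) {
    fitted_mean /= nsave;
    for (int t = 0; t < nterms; ++t) u_mean[t] /= nsave;
  }
  List u_out(nterms);
  for (int t = 0; t < nterms; ++t) u_out[t] = arma::mat(u_mean[t].t());
  return List::create(_["samples"] = out,
                      _["fitted"] = fitted_mean,
                      _["u_mean"] = u_out,
                      _["nsave"] = nsave);
}
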