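// Full-information maximum likelihood for twin-pair ACE covariance models.
//
// The model for a pair is a 2p-variate normal with
//   Sigma = [ A + C + E     rz*A + C  ]
//           [ rz*A + C      A + C + E ]
// where A, C, E are p x p component covariance matrices (additive genetic,
// common environment, unique environment) and rz is the zygosity-specific
// cross-twin genetic correlation (1 for MZ, 0.5 for DZ).
//
// Families are grouped by (zygosity, missingness pattern); each group shares
// one observed submatrix of Sigma, so the Cholesky/inverse is computed once
// per group per likelihood evaluation.  Parameters are the lower-triangular
// Cholesky factors Ga, Gc, Ge of A, C, E (which keeps the components PSD
// without box constraints), per-phenotype means, and optionally per-phenotype
// linear age slopes.  Analytic gradients are returned alongside the negative
// log-likelihood; the voxel-wise driver depends on this being fast.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// unpack vech (column-major lower triangle) into a lower-triangular matrix
static arma::mat vech_to_lower(const arma::vec& v, int p, int offset) {
  arma::mat L(p, p, arma::fill::zeros);
  int k = offset;
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i)
      L(i, j) = v[k++];
  return L;
}

// theta layout: [vech(Ga), vech(Gc), vech(Ge), mu(p), beta(p) if use_age]
// groups: list of list(rz, idx (0-based into 1..2p), Y (n x k),
//                      age (n x k or NULL), n, ybar (k), Scent (k x k))
// Without an age covariate the group means are constant, so the likelihood
// only needs the per-group sufficient statistics (n, ybar, centered scatter);
// with it, the row-wise path is used.
// [[Rcpp::export(name = ".fiml_eval_cpp")]]
List fiml_eval_cpp(const arma::vec& theta, int p, List groups,
                   bool use_age, bool want_grad) {
  const int m = p * (p + 1) / 2;
  arma::mat Ga = vech_to_lower(theta, p, 0);
  arma::mat Gc = vech_to_lower(theta, p, m);
  arma::mat Ge = vech_to_lower(theta, p, 2 * m);
  arma::vec mu = theta.subvec(3 * m, 3 * m + p - 1);
  arma::vec beta(p, arma::fill::zeros);
  if (use_age) beta = theta.subvec(3 * m + p, 3 * m + 2 * p - 1);

  arma::mat A = Ga * Ga.t();
  arma::mat C = Gc * Gc.t();
  arma::mat E = Ge * Ge.t();
  arma::mat W = A + C + E;

  const int P2 = 2 * p;
  double nll = 0.0;
  bool ok = true;

  // gradient accumulators
  arma::mat Va(p, p, arma::fill::zeros), Vc(p, p, arma::fill::zeros),
            Ve(p, p, arma::fill::zeros);
  arma::vec gmu(p, arma::fill::zeros), gbeta(p, arma::fill::zeros);

  int ngroups = groups.size();
  for (int g = 0; g < ngroups && ok; ++g) {
    List grp = groups[g];
    double rz = as<double>(grp["rz"]);
    arma::uvec idx = as<arma::uvec>(grp["idx"]);   // 0-based
    const int k = idx.n_elem;
    bool has_age = use_age && grp.containsElementNamed("age") &&
                   !Rf_isNull(grp["age"]);

    // expected covariance for this zygosity, observed submatrix
    arma::mat X = rz * A + C;
    arma::mat Sigma(P2, P2);
    Sigma.submat(0, 0, p - 1, p - 1) = W;
    Sigma.submat(p, p, P2 - 1, P2 - 1) = W;
    Sigma.submat(0, p, p - 1, P2 - 1) = X;
    Sigma.submat(p, 0, P2 - 1, p - 1) = X;
    arma::mat So = Sigma.submat(idx, idx);

    arma::mat Cf;
    if (!arma::chol(Cf, So)) { ok = false; break; }
    double logdet = 2.0 * arma::sum(arma::log(Cf.diag()));
    arma::mat M;
    if (!arma::inv_sympd(M, So)) { ok = false; break; }

    arma::mat Wg;           // 2 * d nll / d So
    arma::vec gmu_loc(k, arma::fill::zeros);
    int n;

    if (!has_age) {
      // sufficient-statistic path: constant group mean
      n = as<int>(grp["n"]);
      arma::vec ybar = as<arma::vec>(grp["ybar"]);
      arma::mat Scent = as<arma::mat>(grp["Scent"]);
      arma::vec d(k);
      for (int c = 0; c < k; ++c) d[c] = ybar[c] - mu[idx[c] % p];
      arma::vec Md = M * d;
      double quad = arma::accu(M % Scent) + n * arma::dot(d, Md);
      nll += 0.5 * (n * (k * LOG2PI + logdet) + quad);
      if (want_grad) {
        Wg = n * M - M * Scent * M - n * (Md * Md.t());
        gmu_loc = -double(n) * Md;
      }
    } else {
      arma::mat Y = as<arma::mat>(grp["Y"]);
      n = Y.n_rows;
      arma::mat Age = as<arma::mat>(grp["age"]);
      arma::mat MU(n, k);
      for (int c = 0; c < k; ++c) {
        int ph = idx[c] % p;
        for (int r = 0; r < n; ++r)
          MU(r, c) = mu[ph] + beta[ph] * Age(r, c);
      }
      arma::mat Rres = Y - MU;
      arma::mat Q = Rres * M;                     // n x k
      double quad = arma::accu(Q % Rres);
      nll += 0.5 * (n * (k * LOG2PI + logdet) + quad);
      if (want_grad) {
        arma::mat Sxx = Rres.t() * Rres;
        Wg = n * M - M * Sxx * M;
        arma::rowvec colsum = arma::sum(Q, 0);
        for (int c = 0; c < k; ++c) {
          gmu_loc[c] = -colsum[c];
          gbeta[idx[c] % p] -= arma::dot(Age.col(c), Q.col(c));
        }
      }
    }

    if (want_grad) {
      // scatter into full 2p x 2p
      arma::mat Wf(P2, P2, arma::fill::zeros);
      for (int r = 0; r < k; ++r)
        for (int c = 0; c < k; ++c)
          Wf(idx[r], idx[c]) = Wg(r, c);
      arma::mat Wwithin = Wf.submat(0, 0, p - 1, p - 1) +
                          Wf.submat(p, p, P2 - 1, P2 - 1);
      arma::mat Wcross = Wf.submat(0, p, p - 1, P2 - 1) +
                         Wf.submat(p, 0, P2 - 1, p - 1);
      Va += 0.5 * (Wwithin + rz * Wcross);
      Vc += 0.5 * (Wwithin + Wcross);
      Ve += 0.5 * Wwithin;
      for (int c = 0; c < k; ++c) gmu[idx[c] % p] += gmu_loc[c];
    }
  }

  if (!ok) {
    return List::create(_["nll"] = R_PosInf, _["grad"] = R_NilValue,
                        _["ok"] = false);
  }
  if (!want_grad) {
    return List::create(_["nll"] = nll, _["grad"] = R_NilValue, _["ok"] = true);
  }

  // d nll / d G[i,j] = 2 * (V %*% G)[i,j] restricted to the lower triangle
  // (V accumulated with the 1/2 factor already applied, dA = u v' + v u')
  arma::mat Da = 2.0 * (Va * Ga);
  arma::mat Dc = 2.0 * (Vc * Gc);
  arma::mat De = 2.0 * (Ve * Ge);
  arma::vec grad(theta.n_elem, arma::fill::zeros);
  int kk = 0;
  for (int j = 0; j < p; ++j) for (int i = j; i < p; ++i) grad[kk++] = Da(i, j);
  for (int j = 0; j < p; ++j) for (int i = j; i < p; ++i) grad[kk++] = Dc(i, j);
  for (int j = 0; j < p; ++j) for (int i = j; i < p; ++i) grad[kk++] = De(i, j);
  for (int i = 0; i < p; ++i) grad[kk++] = gmu[i];
  if (use_age) for (int i = 0; i < p; ++i) grad[kk++] = gbeta[i];

  return List::create(_["nll"] = nll, _["grad"] = grad, _["ok"] = true);
}

// Equality-constraint values g_i = tr(Wa_i A) + tr(Wc_i C) + tr(We_i E)
// (weight matrices symmetric, zero where a component is excluded) and their
// Jacobian in the Cholesky parameterization: d tr(W G G')/dG = 2 W G.
// [[Rcpp::export(name = ".constraint_eval_cpp")]]
List constraint_eval_cpp(const arma::vec& theta, int p, List Wa, List Wc,
                         List We, bool want_jac) {
  const int m = p * (p + 1) / 2;
  arma::mat G[3] = { vech_to_lower(theta, p, 0),
                     vech_to_lower(theta, p, m),
                     vech_to_lower(theta, p, 2 * m) };
  arma::mat Mcomp[3];
  for (int c = 0; c < 3; ++c) Mcomp[c] = G[c] * G[c].t();
  const int nc = Wa.size();
  arma::vec g(nc, arma::fill::zeros);
  arma::mat J(nc, theta.n_elem, arma::fill::zeros);
  for (int i = 0; i < nc; ++i) {
    List Ws = List::create(Wa[i], Wc[i], We[i]);
    for (int c = 0; c < 3; ++c) {
      arma::mat Wm = as<arma::mat>(Ws[c]);
      if (arma::accu(arma::abs(Wm)) == 0) continue;
      g[i] += arma::accu(Wm % Mcomp[c]);
      if (want_jac) {
        arma::mat D = 2.0 * Wm * G[c];
        int kk = c * m;
        for (int col = 0; col < p; ++col)
          for (int row = col; row < p; ++row)
            J(i, kk++) = D(row, col);
      }
    }
  }
  return List::create(_["g"] = g, _["J"] = J);
}
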