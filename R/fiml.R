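#' Per-family wide phenotype matrix for twin modeling
#'
#' Reshapes a cohort table (one row per individual-occasion) into one row per
#' family with \code{2p} columns: twin 1's phenotypes followed by twin 2's,
#' phenotypes ordered occasion-major (for the default longitudinal set:
#' hormone age 9, density age 9, hormone age 12, density age 12).  Values are
#' \code{NA} wherever an individual-occasion or measurement is missing; a
#' singleton pair simply has its second half missing.
#'
#' @param cohort a \code{twin_cohort}; the \code{hormone} column must have
#'   been prepared (see \code{\link{prepare_hormone}}).
#' @param vars phenotype columns of \code{cohort$data}, within-occasion order.
#' @param occasions occasions to include (1, 2, or both).
#' @param sex optional stratum filter.
#' @return an object of class \code{twin_phenotypes}: list with \code{Y}
#'   (n_families x 2p), \code{age} (matching age values, centred per
#'   occasion), \code{age_centers}, \code{families}, \code{p},
#'   \code{row_index} (cohort row behind each cell, for voxel substitution).
#' @export
twin_phenotypes <- function(cohort, vars = c("hormone", "density"),
                            occasions = c(1, 2), sex = NULL) {
  d <- if (inherits(cohort, "twin_cohort")) cohort$data else cohort
  miss <- setdiff(vars, names(d))
  if (length(miss))
    stop("cohort is missing phenotype column(s): ",
         paste(miss, collapse = ", "),
         if ("hormone" %in% miss) " (run prepare_hormone first)" else "")
  if (!is.null(sex)) d <- d[d$sex %in% sex, , drop = FALSE]
  fams <- unique(d[, c("family_id", "zygosity")])
  fams <- fams[order(fams$family_id), , drop = FALSE]
  rownames(fams) <- NULL
  p <- length(vars) * length(occasions)
  n <- nrow(fams)
  Y <- matrix(NA_real_, n, 2 * p)
  Age <- matrix(NA_real_, n, 2 * p)
  Ridx <- matrix(NA_integer_, n, 2 * p)
  centers <- vapply(occasions, function(o) {
    a <- d$age[d$occasion == o]
    if (length(a)) mean(a, na.rm = TRUE) else 0
  }, numeric(1))
  fi <- match(d$family_id, fams$family_id)
  for (r in seq_len(nrow(d))) {
    o <- match(d$occasion[r], occasions)
    if (is.na(o)) next
    t <- d$twin_id[r]
    if (!t %in% c(1, 2)) stop("twin_id must be 1 or 2")
    for (v in seq_along(vars)) {
      ph <- (o - 1) * length(vars) + v
      col <- (t - 1) * p + ph
      Y[fi[r], col] <- d[[vars[v]]][r]
      Age[fi[r], col] <- d$age[r] - centers[o]
      Ridx[fi[r], col] <- r
    }
  }
  labels <- as.vector(t(outer(occasions, vars,
                              function(o, v) paste0(v, "_occ", o))))
  out <- list(Y = Y, age = Age, age_centers = centers, families = fams,
              p = p, labels = labels, row_index = Ridx,
              vars = vars, occasions = occasions)
  class(out) <- "twin_phenotypes"
  out
}

# group families by (zygosity, missingness pattern); shared observed
# submatrices make the FIML evaluation cheap
build_groups <- function(ph, age_covariate = FALSE) {
  obs <- !is.na(ph$Y)
  keep <- rowSums(obs) > 0
  Y <- ph$Y[keep, , drop = FALSE]
  Age <- ph$age[keep, , drop = FALSE]
  Ridx <- ph$row_index[keep, , drop = FALSE]
  fams <- ph$families[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- paste(fams$zygosity, apply(obs, 1, paste, collapse = ""))
  groups <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    idx <- which(obs[rows[1], ])
    age <- Age[rows, idx, drop = FALSE]
    age[is.na(age)] <- 0
    Yg <- Y[rows, idx, drop = FALSE]
    ybar <- colMeans(Yg)
    Yc <- sweep(Yg, 2, ybar)
    list(rz = zygosity_rule(fams$zygosity[rows[1]]),
         idx = as.integer(idx - 1L),
         Y = Yg,
         n = length(rows), ybar = ybar, Scent = crossprod(Yc),
         age = if (age_covariate) age else NULL,
         row_index = Ridx[rows, idx, drop = FALSE],
         families = fams$family_id[rows])
  })
  attr(groups, "n_families") <- nrow(Y)
  attr(groups, "n_obs") <- sum(obs)
  groups
}

# ---- parameter packing -----------------------------------------------------

vech <- function(M) M[lower.tri(M, diag = TRUE)]

lower_from_vech <- function(v, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

n_chol <- function(p) p * (p + 1) / 2

theta_length <- function(p, age) 3 * n_chol(p) + p + if (age) p else 0

safe_chol_lower <- function(M, floor_frac = 1e-6) {
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  lo <- max(mean(abs(es$values)), 1e-8) * floor_frac
  vals <- pmax(es$values, lo)
  t(chol(es$vectors %*% diag(vals, length(vals)) %*% t(es$vectors)))
}

theta_pack <- function(A, C, E, mu, beta = NULL) {
  c(vech(safe_chol_lower(A)), vech(safe_chol_lower(C)),
    vech(safe_chol_lower(E)), mu, beta)
}

theta_components <- function(theta, p) {
  m <- n_chol(p)
  Ga <- lower_from_vech(theta[1:m], p)
  Gc <- lower_from_vech(theta[(m + 1):(2 * m)], p)
  Ge <- lower_from_vech(theta[(2 * m + 1):(3 * m)], p)
  list(A = Ga %*% t(Ga), C = Gc %*% t(Gc), E = Ge %*% t(Ge),
       mu = theta[(3 * m + 1):(3 * m + p)],
       beta = if (length(theta) >= 3 * m + 2 * p)
         theta[(3 * m + p + 1):(3 * m + 2 * p)] else NULL)
}

theta_to_model <- function(theta, p, labels = NULL) {
  cm <- theta_components(theta, p)
  path_model_from_components(cm$A, cm$C, cm$E, means = cm$mu,
                             age_slopes = cm$beta, phenotypes = labels)
}

# moment-based starting values from per-zygosity pairwise-complete covariances
moment_start <- function(ph, age_covariate = FALSE) {
  p <- ph$p
  block_cov <- function(zyg) {
    Yz <- ph$Y[ph$families$zygosity == zyg, , drop = FALSE]
    if (nrow(Yz) < 3) return(NULL)
    S <- suppressWarnings(stats::cov(Yz, use = "pairwise.complete.obs"))
    S[!is.finite(S)] <- 0
    W <- (S[1:p, 1:p] + S[p + 1:p, p + 1:p]) / 2
    X <- (S[1:p, p + 1:p] + t(S[1:p, p + 1:p]) +
            S[p + 1:p, 1:p] + t(S[p + 1:p, 1:p])) / 4
    list(W = (W + t(W)) / 2, X = X, n = nrow(Yz))
  }
  mz <- block_cov("MZ"); dz <- block_cov("DZ")
  vtot <- apply(rbind(ph$Y[, 1:p, drop = FALSE], ph$Y[, p + 1:p, drop = FALSE]),
                2, stats::var, na.rm = TRUE)
  vtot[!is.finite(vtot) | vtot <= 0] <- 1
  W <- if (!is.null(mz) && !is.null(dz)) {
    (mz$W * mz$n + dz$W * dz$n) / (mz$n + dz$n)
  } else if (!is.null(mz)) mz$W else if (!is.null(dz)) dz$W else diag(vtot, p)
  if (!is.null(mz) && !is.null(dz)) {
    A <- 2 * (mz$X - dz$X)
    C <- 2 * dz$X - mz$X
  } else {
    A <- 0.4 * W; C <- 0.2 * W
  }
  E <- W - A - C
  mu <- colMeans(rbind(ph$Y[, 1:p, drop = FALSE],
                       ph$Y[, p + 1:p, drop = FALSE]), na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  # keep the starting E well conditioned: moment estimates of A and C can
  # overshoot, leaving W - A - C indefinite and the pair covariance singular
  clip_eigen <- function(M, lo) {
    es <- eigen((M + t(M)) / 2, symmetric = TRUE)
    es$vectors %*% diag(pmax(es$values, lo), p) %*% t(es$vectors)
  }
  scale <- mean(pmax(diag(W), 1e-3))
  A <- clip_eigen(A, 1e-4 * scale)
  C <- clip_eigen(C, 1e-4 * scale)
  E <- clip_eigen(E, 0.1 * scale)
  theta_pack(A, C, E, mu,
             beta = if (age_covariate) rep(0, p) else NULL)
}

# ---- constraints -----------------------------------------------------------

supported_constraints <- c("none", "change_corr_zero", "cross_trait_age12_zero",
                           "rph_a_zero", "rph_c_zero", "rph_e_zero")

# scalar constraint value from the component covariance matrices; indices for
# p = 4 follow the fixed phenotype order (h9, d9, h12, d12); for the
# bivariate age-12 model (p = 2) the order is (h12, d12)
constraint_value <- function(constraint, cm, p, target) {
  chpart <- function(M) M[3, 4] + M[1, 2] - M[1, 4] - M[2, 3]
  xpart <- function(M) if (p == 4) M[3, 4] else M[1, 2]
  total <- cm$A + cm$C + cm$E
  comp_part <- function(M) {
    if (target == "change" && p == 4) chpart(M) else xpart(M)
  }
  switch(constraint,
    change_corr_zero = {
      if (p != 4) stop("change_corr_zero needs the 4-phenotype model")
      chpart(total)
    },
    cross_trait_age12_zero = xpart(total),
    rph_a_zero = comp_part(cm$A),
    rph_c_zero = comp_part(cm$C),
    rph_e_zero = comp_part(cm$E),
    stop("unknown constraint: ", constraint))
}

constraint_fun <- function(constraints, p, target) {
  zero <- matrix(0, p, p)
  Wa <- Wc <- We <- vector("list", length(constraints))
  for (i in seq_along(constraints)) {
    cw <- constraint_weight(constraints[i], p, target)
    Wa[[i]] <- if ("a" %in% cw$comps) cw$W else zero
    Wc[[i]] <- if ("c" %in% cw$comps) cw$W else zero
    We[[i]] <- if ("e" %in% cw$comps) cw$W else zero
  }
  function(theta, want_jac = FALSE) {
    r <- .constraint_eval_cpp(theta, p, Wa, Wc, We, want_jac)
    if (want_jac) r else drop(r$g)
  }
}

# every supported constraint is tr(W %*% M) over one or more component
# covariance matrices M = G G', with a fixed symmetric weight matrix W
constraint_weight <- function(constraint, p, target) {
  W <- matrix(0, p, p)
  add <- function(W, i, j, w) { W[i, j] <- W[i, j] + w / 2
                                W[j, i] <- W[j, i] + w / 2; W }
  if (p == 4 && target == "change" &&
      constraint %in% c("change_corr_zero", "rph_a_zero", "rph_c_zero",
                        "rph_e_zero")) {
    W <- add(W, 3, 4, 1); W <- add(W, 1, 2, 1)
    W <- add(W, 1, 4, -1); W <- add(W, 2, 3, -1)
  } else if (p == 4) {
    W <- add(W, 3, 4, 1)
  } else {
    W <- add(W, 1, 2, 1)
  }
  comps <- switch(constraint,
                  change_corr_zero = ,
                  cross_trait_age12_zero = c("a", "c", "e"),
                  rph_a_zero = "a", rph_c_zero = "c", rph_e_zero = "e")
  list(W = W, comps = comps)
}


# ---- likelihood ------------------------------------------------------------

fiml_nll_groups <- function(theta, p, groups, age) {
  r <- .fiml_eval_cpp(theta, p, groups, age, FALSE)
  if (!r$ok) return(Inf)
  r$nll
}

fiml_grad_groups <- function(theta, p, groups, age) {
  r <- .fiml_eval_cpp(theta, p, groups, age, TRUE)
  if (!r$ok) return(rep(0, length(theta)))
  r$grad
}

#' Full-information maximum likelihood of a path model given twin data
#'
#' Each family contributes the multivariate-normal log-density of exactly its
#' observed phenotype subvector, with mean and covariance taken as the
#' corresponding subvector/submatrix of the model-implied 2p-variate mean and
#' covariance (\code{\link{expected_cov}}).  Implemented directly in R from
#' the model matrices; \code{\link{fit_ace}} maximizes an equivalent compiled
#' objective.
#'
#' @param model a \code{\link{path_model}}.
#' @param ph a \code{\link{twin_phenotypes}} object (or a \code{twin_cohort},
#'   converted with defaults).
#' @param age_covariate include the per-phenotype linear age term of the
#'   model's \code{age_slopes} in the means.
#' @return the log-likelihood (scalar).
#' @export
fiml_loglik <- function(model, ph, age_covariate = FALSE) {
  if (inherits(ph, "twin_cohort")) ph <- twin_phenotypes(ph)
  p <- ph$p
  if (length(model$a) != p) stop("model has wrong number of phenotypes")
  sig <- list(MZ = expected_cov(model, "MZ"), DZ = expected_cov(model, "DZ"))
  mu2 <- rep(model$means, 2)
  slopes <- if (age_covariate) {
    if (is.null(model$age_slopes)) stop("model has no age_slopes")
    rep(model$age_slopes, 2)
  } else NULL
  ll <- 0
  for (f in seq_len(nrow(ph$Y))) {
    y <- ph$Y[f, ]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    S <- sig[[ph$families$zygosity[f]]][obs, obs, drop = FALSE]
    m <- mu2[obs]
    if (!is.null(slopes)) {
      a <- ph$age[f, obs]; a[is.na(a)] <- 0
      m <- m + slopes[obs] * a
    }
    Cf <- tryCatch(chol(S), error = function(e)
      stop("singular observed submatrix for family ",
           ph$families$family_id[f]))
    z <- backsolve(Cf, y[obs] - m, transpose = TRUE)
    ll <- ll - 0.5 * (length(obs) * log(2 * pi) +
                        2 * sum(log(diag(Cf))) + sum(z^2))
  }
  ll
}

# run an expression with a private RNG stream, restoring the caller's state
local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

optimize_theta <- function(theta0, p, groups, age, gfun = NULL,
                           maxit = 500, reltol = 1e-10) {
  fn <- function(th) {
    v <- fiml_nll_groups(th, p, groups, age)
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(th) fiml_grad_groups(th, p, groups, age)
  if (is.null(gfun)) {
    opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
    return(list(theta = opt$par, nll = opt$value,
                converged = opt$convergence == 0, g = numeric(0)))
  }
  # augmented-Lagrangian handling of nonlinear equality constraints:
  # multiplier updates at moderate penalty, penalty growth only when the
  # constraint violation stalls
  theta <- theta0
  lambda <- 1000; mual <- rep(0, length(gfun(theta0)))
  conv <- FALSE
  g_prev <- Inf
  for (outer in 1:15) {
    obj <- function(th) {
      v <- fn(th)
      g <- gfun(th)
      v + sum(mual * g) + 0.5 * lambda * sum(g^2)
    }
    grd <- function(th) {
      r <- gfun(th, want_jac = TRUE)
      gr(th) + drop(t(r$J) %*% (mual + lambda * drop(r$g)))
    }
    opt <- stats::optim(theta, obj, grd, method = "BFGS",
                        control = list(maxit = maxit,
                                       reltol = if (outer < 3) 1e-8 else reltol))
    theta <- opt$par
    g <- gfun(theta)
    conv <- opt$convergence == 0
    if (max(abs(g)) < 1e-8) break
    mual <- mual + lambda * g
    if (max(abs(g)) > 0.25 * g_prev || max(abs(g)) < 1e-6)
      lambda <- lambda * 10
    g_prev <- max(abs(g))
  }
  list(theta = theta, nll = fn(theta), converged = conv && max(abs(g)) < 1e-8,
       g = g)
}

#' Fit the ACE twin model by full-information maximum likelihood
#'
#' Maximizes the FIML likelihood over all path-model parameters, optionally
#' subject to nonlinear equality constraints (handled by an augmented
#' Lagrangian driven to |g| < 1e-8).  Component covariance matrices are
#' parameterized by their Cholesky factors, which keeps them positive
#' semidefinite throughout; results are reported in correlated-factor form
#' (paths plus factor correlation matrices).  Several seeded starts are used:
#' the first from per-zygosity moment estimates, the rest randomly perturbed;
#' the best converged likelihood wins, ties broken by parameter norm.
#'
#' @param ph a \code{\link{twin_phenotypes}} object or a \code{twin_cohort}
#'   (converted with the default longitudinal phenotype set).
#' @param constraint subset of \code{"none"}, \code{"change_corr_zero"},
#'   \code{"cross_trait_age12_zero"}, \code{"rph_a_zero"},
#'   \code{"rph_c_zero"}, \code{"rph_e_zero"}.
#' @param target decomposition target for the component-zeroing constraints:
#'   \code{"change"} or \code{"age12_cross_trait"}.
#' @param n_starts number of optimizer starts.
#' @param age_covariate estimate a per-phenotype linear age slope in the
#'   means (the means are then intercepts at the per-occasion mean age).
#' @param seed integer seed for the random restarts (does not disturb the
#'   caller's RNG state).
#' @param start optional explicit starting parameter vector (used first).
#' @return an object of class \code{ace_fit}: \code{model} (fitted
#'   \code{\link{path_model}}), \code{loglik}, \code{n_params},
#'   \code{converged}, \code{constraint}, \code{target}, \code{theta},
#'   \code{n_families}.
#' @export
fit_ace <- function(ph, constraint = "none", target = "change",
                    n_starts = 5, age_covariate = FALSE, seed = 1L,
                    start = NULL) {
  if (inherits(ph, "twin_cohort")) ph <- twin_phenotypes(ph)
  constraint <- unique(constraint)
  if (!all(constraint %in% supported_constraints))
    stop("unsupported constraint(s): ",
         paste(setdiff(constraint, supported_constraints), collapse = ", "))
  constraint <- setdiff(constraint, "none")
  target <- match.arg(target, c("change", "age12_cross_trait"))
  p <- ph$p
  groups <- build_groups(ph, age_covariate)
  if (attr(groups, "n_families") == 0) stop("cohort has no observed data")
  gfun <- if (length(constraint))
    constraint_fun(constraint, p, if (target == "change") "change" else "age12")
  else NULL

  theta0 <- moment_start(ph, age_covariate)
  starts <- if (is.null(start)) list(theta0)
            else if (n_starts <= 1) list(start)
            else list(start, theta0)
  extra <- n_starts - length(starts)
  if (extra > 0) {
    jit <- local_seed(seed, matrix(stats::rnorm(extra * length(theta0), 0, 0.25),
                                   extra, length(theta0)))
    scale <- pmax(abs(theta0), 0.2)
    for (i in seq_len(extra))
      starts[[length(starts) + 1]] <- theta0 + jit[i, ] * scale
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(optimize_theta(s, p, groups, age_covariate, gfun),
                    error = function(e) NULL)
    if (is.null(res)) next
    better <- is.null(best) ||
      (res$converged && !best$converged) ||
      (res$converged == best$converged &&
         (res$nll < best$nll - 1e-9 ||
            (abs(res$nll - best$nll) <= 1e-9 &&
               sum(res$theta^2) < sum(best$theta^2))))
    if (better) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  fit <- list(model = theta_to_model(best$theta, p, ph$labels),
              loglik = -best$nll,
              n_params = theta_length(p, age_covariate) - length(constraint),
              converged = best$converged,
              constraint = if (length(constraint)) constraint else "none",
              target = target, theta = best$theta,
              constraint_value = best$g,
              n_families = attr(groups, "n_families"),
              age_covariate = age_covariate, p = p)
  class(fit) <- "ace_fit"
  fit
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE FIML fit: %d phenotypes, %d families, loglik %.3f (%s)\n",
              x$p, x$n_families, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat("  constraint:", paste(x$constraint, collapse = ", "), "\n")
  print(x$model)
  invisible(x)
}

#' Likelihood-ratio test of nested FIML fits
#'
#' Minus twice the log-likelihood difference, referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in free
#' parameters (one per single equality constraint).  Negative differences
#' from optimizer noise are clipped at zero.
#'
#' @param full unconstrained (or less constrained) \code{ace_fit}.
#' @param constrained nested \code{ace_fit}.
#' @return list of class \code{lrt_result}: \code{chi2}, \code{df}, \code{p}.
#' @export
lrt <- function(full, constrained) {
  df <- full$n_params - constrained$n_params
  if (df <= 0) stop("constrained model must have fewer free parameters")
  chi2 <- max(0, 2 * (full$loglik - constrained$loglik))
  out <- list(chi2 = chi2, df = df,
              p = stats::pchisq(chi2, df, lower.tail = FALSE))
  class(out) <- "lrt_result"
  out
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Bivariate ACE model at age 12 only
#'
#' The submodel using only the age-12 hormone and density phenotypes
#' (2 phenotypes x 2 twins, 4x4 expected covariance), with the same
#' constraint and likelihood-ratio machinery; the cross-trait covariance
#' decomposes as \code{a3 rg a4 + c3 rc c4 + e3 re e4}.
#'
#' @param cohort a \code{twin_cohort} (the hormone column must be prepared)
#'   or a \code{twin_phenotypes} built on occasion 2 only.
#' @param constraint as in \code{\link{fit_ace}} (\code{"change_corr_zero"}
#'   is not available for this model).
#' @param ... passed to \code{\link{fit_ace}}.
#' @return an \code{ace_fit} with \code{p = 2}.
#' @export
fit_bivariate_age12 <- function(cohort, constraint = "none", ...) {
  ph <- if (inherits(cohort, "twin_cohort"))
    twin_phenotypes(cohort, occasions = 2) else cohort
  if (ph$p != 2) stop("expected a 2-phenotype (age-12 only) layout")
  fit_ace(ph, constraint = constraint, target = "age12_cross_trait", ...)
}
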