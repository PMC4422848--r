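#' Correlated-factor ACE path model
#'
#' Container for the structural twin model underlying all analyses in the
#' package: each of \code{p} phenotypes loads on its own additive-genetic (A),
#' common-environment (C) and unique-environment (E) factor through path
#' coefficients \code{a}, \code{c}, \code{e}; factors of the same kind are
#' correlated across phenotypes through the correlation matrices \code{R_g},
#' \code{R_c} and \code{R_e}.  Across the two members of a twin pair, A
#' factors correlate 1 (monozygotic) or 0.5 (dizygotic), C factors correlate
#' 1 by definition, and E factors are uncorrelated.
#'
#' The default phenotype order for the longitudinal four-variate model is
#' fixed throughout the package: 1 = hormone at age 9, 2 = grey-matter
#' density at age 9, 3 = hormone at age 12, 4 = density at age 12.
#'
#' @param a,c,e numeric path-coefficient vectors, one entry per phenotype.
#'   \code{e} must be strictly positive (unique environment absorbs
#'   measurement error, so its variance cannot vanish).
#' @param R_g,R_c,R_e factor correlation matrices (symmetric, unit diagonal,
#'   positive semidefinite).  Default: identity.
#' @param means phenotype means (default 0).
#' @param age_slopes optional per-phenotype linear age slopes for the means
#'   model (used when fitting with an age covariate).
#' @param phenotypes character labels.
#' @return an object of class \code{path_model}.
#' @export
path_model <- function(a, c, e, R_g = NULL, R_c = NULL, R_e = NULL,
                       means = NULL, age_slopes = NULL, phenotypes = NULL) {
  p <- length(a)
  if (is.null(R_g)) R_g <- diag(p)
  if (is.null(R_c)) R_c <- diag(p)
  if (is.null(R_e)) R_e <- diag(p)
  if (is.null(means)) means <- rep(0, p)
  if (is.null(phenotypes)) {
    phenotypes <- if (p == 4) {
      c("hormone_9", "density_9", "hormone_12", "density_12")
    } else paste0("phenotype_", seq_len(p))
  }
  m <- structure(
    list(a = as.numeric(a), c = as.numeric(c), e = as.numeric(e),
         R_g = unname(as.matrix(R_g)), R_c = unname(as.matrix(R_c)),
         R_e = unname(as.matrix(R_e)), means = as.numeric(means),
         age_slopes = if (is.null(age_slopes)) NULL else as.numeric(age_slopes),
         phenotypes = phenotypes),
    class = "path_model")
  validate_path_model(m)
  m
}

#' @export
print.path_model <- function(x, ...) {
  p <- length(x$a)
  cat("ACE path model (", p, " phenotypes)\n", sep = "")
  tab <- rbind(a2 = x$a^2, c2 = x$c^2, e2 = x$e^2, mean = x$means)
  colnames(tab) <- x$phenotypes
  print(round(tab, 3))
  invisible(x)
}

validate_corr <- function(R, p, name) {
  if (!is.matrix(R) || nrow(R) != p || ncol(R) != p)
    stop(name, " must be a ", p, "x", p, " matrix")
  if (max(abs(R - t(R))) > 1e-8) stop(name, " must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop(name, " must have unit diagonal")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(name, " must be positive semidefinite")
  invisible(TRUE)
}

validate_path_model <- function(m) {
  p <- length(m$a)
  if (length(m$c) != p || length(m$e) != p || length(m$means) != p)
    stop("a, c, e and means must have equal length")
  if (any(!is.finite(c(m$a, m$c, m$e, m$means))))
    stop("path coefficients and means must be finite")
  if (any(m$e <= 0)) stop("e paths must be strictly positive")
  validate_corr(m$R_g, p, "R_g")
  validate_corr(m$R_c, p, "R_c")
  validate_corr(m$R_e, p, "R_e")
  if (!is.null(m$age_slopes) && length(m$age_slopes) != p)
    stop("age_slopes must have one entry per phenotype")
  invisible(TRUE)
}

#' A, C and E component covariance matrices of a path model
#'
#' \code{A = diag(a) R_g diag(a)} and likewise for C and E; the phenotypic
#' covariance of one individual is \code{A + C + E}.
#'
#' @param model a \code{\link{path_model}}.
#' @return list with elements \code{A}, \code{C}, \code{E}.
#' @export
ace_components <- function(model) {
  validate_path_model(model)
  list(A = diag(model$a, length(model$a)) %*% model$R_g %*% diag(model$a, length(model$a)),
       C = diag(model$c, length(model$c)) %*% model$R_c %*% diag(model$c, length(model$c)),
       E = diag(model$e, length(model$e)) %*% model$R_e %*% diag(model$e, length(model$e)))
}

#' Rebuild a path model from component covariance matrices
#'
#' Inverse of \code{\link{ace_components}}: paths are the square roots of the
#' component variances (\code{e} forced positive) and the factor correlation
#' matrices are the component correlation matrices.  A phenotype with zero A
#' (or C) variance gets zero correlations with the other factors of that kind.
#'
#' @param A,C,E component covariance matrices.
#' @param means phenotype means.
#' @param age_slopes optional age slopes.
#' @param phenotypes labels.
#' @return a \code{\link{path_model}}.
#' @export
path_model_from_components <- function(A, C, E, means = NULL,
                                       age_slopes = NULL, phenotypes = NULL) {
  safe_cor <- function(M) {
    d <- sqrt(pmax(diag(M), 0))
    R <- diag(1, nrow(M))
    nz <- which(d > 1e-12)
    if (length(nz) > 1)
      R[nz, nz] <- M[nz, nz] / (d[nz] %o% d[nz])
    diag(R) <- 1
    (R + t(R)) / 2
  }
  path_model(a = sqrt(pmax(diag(A), 0)), c = sqrt(pmax(diag(C), 0)),
             e = sqrt(pmax(diag(E), 1e-12)),
             R_g = safe_cor(A), R_c = safe_cor(C), R_e = safe_cor(E),
             means = means, age_slopes = age_slopes, phenotypes = phenotypes)
}

#' Model-implied covariance matrix of a twin pair
#'
#' Returns the \code{2p x 2p} covariance of the stacked phenotype vector
#' (twin 1 phenotypes, then twin 2 phenotypes).  The within-twin block is
#' \code{A + C + E}; the cross-twin block is \code{rz * A + C} with
#' \code{rz = 1} for monozygotic and \code{rz = 0.5} for dizygotic pairs
#' (C correlates 1 across twins by definition, E does not correlate).
#'
#' @param model a \code{\link{path_model}}.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return symmetric positive-semidefinite matrix.
#' @export
expected_cov <- function(model, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  comp <- ace_components(model)
  rz <- zygosity_rule(zygosity)
  W <- comp$A + comp$C + comp$E
  X <- rz * comp$A + comp$C
  rbind(cbind(W, X), cbind(X, W))
}

#' Cross-twin factor correlations by zygosity
#'
#' The additive-genetic cross-twin correlation is 1 in monozygotic and 0.5 in
#' dizygotic pairs; the common-environment correlation is 1 in both.
#'
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return the genetic cross-twin correlation.
#' @export
zygosity_rule <- function(zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  if (zygosity == "MZ") 1.0 else 0.5
}

#' Draw a random valid path model
#'
#' Used for property-style validation: variance shares for A, C and E are
#' drawn from a Dirichlet-like scheme (E bounded away from zero) and factor
#' correlation matrices from a Wishart construction, so every draw satisfies
#' the model invariants.
#'
#' @param p number of phenotypes.
#' @param seed optional integer seed.
#' @return a \code{\link{path_model}}.
#' @export
random_path_model <- function(p = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sh <- matrix(stats::rgamma(3 * p, shape = 2), nrow = 3)
  sh <- sweep(sh, 2, colSums(sh), "/")
  sh[3, ] <- pmax(sh[3, ], 0.1)          # keep e^2 identifiable
  sh <- sweep(sh, 2, colSums(sh), "/")
  rand_corr <- function() {
    Z <- matrix(stats::rnorm((p + 2) * p), p + 2, p)
    stats::cov2cor(crossprod(Z))
  }
  path_model(a = sqrt(sh[1, ]), c = sqrt(sh[2, ]), e = sqrt(sh[3, ]),
             R_g = rand_corr(), R_c = rand_corr(), R_e = rand_corr(),
             means = stats::rnorm(p, 0, 0.5))
}
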