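#' Latent-change covariance algebra
#'
#' The longitudinal four-phenotype model (1 = hormone age 9, 2 = density age
#' 9, 3 = hormone age 12, 4 = density age 12) implies latent change variables
#' for each trait (age-12 minus age-9 latent phenotype).  All change
#' quantities are functions of the fitted paths and factor correlations, not
#' of per-subject difference scores, so they remain defined for subjects
#' observed at a single occasion.
#'
#' @name change_algebra
NULL

# total cross-phenotype covariance implied by the paths:
# a_i r_g(i,j) a_j + c_i r_c(i,j) c_j + e_i r_e(i,j) e_j
cross_cov_term <- function(model, i, j, components = c("a", "c", "e")) {
  out <- 0
  if ("a" %in% components)
    out <- out + model$a[i] * model$R_g[i, j] * model$a[j]
  if ("c" %in% components)
    out <- out + model$c[i] * model$R_c[i, j] * model$c[j]
  if ("e" %in% components)
    out <- out + model$e[i] * model$R_e[i, j] * model$e[j]
  out
}

#' Variance of a latent change variable
#'
#' For the trait measured as phenotype \code{i} at age 9 and phenotype
#' \code{j} at age 12, the latent change variance is
#' \deqn{Var_i + Var_j - 2 (a_i r_g(i,j) a_j + c_i r_c(i,j) c_j +
#'       e_i r_e(i,j) e_j)}
#' with \eqn{Var_k = a_k^2 + c_k^2 + e_k^2}.  The default pair \code{c(2, 4)}
#' is grey-matter density; \code{c(1, 3)} is the hormone.
#'
#' @param model a four-phenotype \code{\link{path_model}}.
#' @param phenotype_pair integer pair \code{c(i, j)}, \code{j} the follow-up
#'   of \code{i}.
#' @return non-negative scalar.
#' @export
change_variance <- function(model, phenotype_pair = c(2, 4)) {
  i <- phenotype_pair[1]; j <- phenotype_pair[2]
  tot <- function(k) model$a[k]^2 + model$c[k]^2 + model$e[k]^2
  tot(i) + tot(j) - 2 * cross_cov_term(model, i, j)
}

#' Covariance between latent hormone change and latent density change
#'
#' The twelve-term expansion
#' \deqn{Cov(ch GM, ch H) = Cov(3,4) + Cov(1,2) - Cov(1,4) - Cov(2,3)}
#' where each \eqn{Cov(i,j)} expands over the A, C and E factor paths.
#' Restricting \code{components} gives the part transmitted through a single
#' factor kind (used by the rph decomposition and the component-zeroing
#' constraints).
#'
#' @param model a four-phenotype \code{\link{path_model}}.
#' @param components subset of \code{c("a", "c", "e")}.
#' @return scalar covariance.
#' @export
change_covariance <- function(model, components = c("a", "c", "e")) {
  cross_cov_term(model, 3, 4, components) +
    cross_cov_term(model, 1, 2, components) -
    cross_cov_term(model, 1, 4, components) -
    cross_cov_term(model, 2, 3, components)
}

#' Decompose a phenotypic correlation into A, C and E contributions
#'
#' \code{rph_a} is the correlation that would be observed if only genetic
#' factors linked the two traits: the genetic part of the covariance divided
#' by the square root of the product of the two total variances.  \code{rph_c}
#' and \code{rph_e} are defined likewise, and the three sum to the full
#' phenotypic correlation.
#'
#' Two targets are supported: \code{"change"} decomposes the correlation
#' between latent hormone change and latent density change;
#' \code{"age12_cross_trait"} decomposes the cross-trait correlation between
#' hormone and density at age 12 (phenotypes 3 and 4).
#'
#' @param model a four-phenotype \code{\link{path_model}}.
#' @param target \code{"change"} or \code{"age12_cross_trait"}.
#' @return an object of class \code{change_stats}: list with \code{V_chGM},
#'   \code{V_chH} (for the change target), \code{Cov}, \code{r},
#'   \code{rph_a}, \code{rph_c}, \code{rph_e}.  When a variance underflows
#'   below \code{1e-10} the correlation and its components are \code{NA}
#'   rather than infinite.
#' @export
rph_decomposition <- function(model, target = c("change", "age12_cross_trait")) {
  target <- match.arg(target)
  p <- length(model$a)
  if (p == 2) {
    # bivariate age-12 submodel: phenotypes are (hormone 12, density 12)
    if (target != "age12_cross_trait")
      stop("a 2-phenotype model only supports the age12_cross_trait target")
    tot <- function(k) model$a[k]^2 + model$c[k]^2 + model$e[k]^2
    v1 <- tot(2); v2 <- tot(1)
    cov_parts <- vapply(c("a", "c", "e"),
                        function(k) cross_cov_term(model, 1, 2, k), numeric(1))
    return(rph_build(target, v1, v2, cov_parts, change = FALSE))
  }
  if (target == "change") {
    v1 <- change_variance(model, c(2, 4))   # density change
    v2 <- change_variance(model, c(1, 3))   # hormone change
    cov_parts <- vapply(c("a", "c", "e"),
                        function(k) change_covariance(model, k), numeric(1))
  } else {
    tot <- function(k) model$a[k]^2 + model$c[k]^2 + model$e[k]^2
    v1 <- tot(4); v2 <- tot(3)
    cov_parts <- vapply(c("a", "c", "e"),
                        function(k) cross_cov_term(model, 3, 4, k), numeric(1))
  }
  rph_build(target, v1, v2, cov_parts, change = target == "change")
}

rph_build <- function(target, v1, v2, cov_parts, change) {
  cov_total <- sum(cov_parts)
  denom_ok <- v1 > 1e-10 && v2 > 1e-10
  denom <- if (denom_ok) sqrt(v1 * v2) else NA_real_
  out <- list(
    target = target,
    V_chGM = if (change) v1 else NA_real_,
    V_chH = if (change) v2 else NA_real_,
    V1 = v1, V2 = v2,
    Cov = cov_total,
    r = if (denom_ok) cov_total / denom else NA_real_,
    rph_a = if (denom_ok) cov_parts[["a"]] / denom else NA_real_,
    rph_c = if (denom_ok) cov_parts[["c"]] / denom else NA_real_,
    rph_e = if (denom_ok) cov_parts[["e"]] / denom else NA_real_)
  class(out) <- "change_stats"
  out
}

#' @export
print.change_stats <- function(x, ...) {
  cat("Correlation decomposition (", x$target, ")\n", sep = "")
  cat(sprintf("  r = %.4f  (rph-a %.4f + rph-c %.4f + rph-e %.4f)\n",
              x$r, x$rph_a, x$rph_c, x$rph_e))
  if (x$target == "change")
    cat(sprintf("  V_chGM = %.4f  V_chH = %.4f  Cov = %.4f\n",
                x$V_chGM, x$V_chH, x$Cov))
  invisible(x)
}
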