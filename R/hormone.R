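#' Creatinine correction of urinary hormone levels
#'
#' Urinary hormone concentrations are divided by the creatinine concentration
#' of the same sample, correcting for variation in urine excretion rate.
#' Salivary hormones (e.g. testosterone) carry no creatinine measurement and
#' pass through unchanged: supply \code{creatinine = NULL}.
#'
#' @param level hormone concentration(s) (U/l or pmol/l); \code{NA} allowed.
#' @param creatinine creatinine concentration(s) (mmol/l), or \code{NULL} for
#'   saliva measures.
#' @return normalized level(s) (U/mmol or pmol/mmol), or \code{level}
#'   unchanged when \code{creatinine} is \code{NULL}.
#' @export
normalize_creatinine <- function(level, creatinine = NULL) {
  if (is.null(creatinine)) return(level)
  bad <- !is.na(creatinine) & creatinine <= 0
  if (any(bad)) stop("creatinine must be positive")
  level / creatinine
}

#' Combine the two assessment days into one phenotype value
#'
#' The per-occasion phenotype is the mean of the two days when both are
#' usable, the single day's value when only one is usable, and missing when
#' neither is (both below the detection limit or absent).  A day is unusable
#' when its below-limit flag is set or its value is missing.
#'
#' @param day1,day2 per-day (already creatinine-corrected) levels.
#' @param below1,below2 logical below-detection-limit flags (default
#'   \code{FALSE}); a flagged day is treated as missing unless an imputed
#'   value was substituted beforehand.
#' @return combined value(s), \code{NA} where neither day is usable.
#' @export
combine_days <- function(day1, day2, below1 = FALSE, below2 = FALSE) {
  n <- max(length(day1), length(day2))
  day1 <- rep_len(day1, n); day2 <- rep_len(day2, n)
  below1 <- rep_len(as.logical(below1), n)
  below2 <- rep_len(as.logical(below2), n)
  d1 <- ifelse(below1 | is.na(day1), NA_real_, day1)
  d2 <- ifelse(below2 | is.na(day2), NA_real_, day2)
  out <- rowMeans(cbind(d1, d2), na.rm = TRUE)
  out[is.na(d1) & is.na(d2)] <- NA_real_
  out
}

#' Natural log transform of hormone levels
#'
#' Raw (creatinine-corrected) hormone levels are strongly left-skewed;
#' analyses are run on the natural-log scale.  Missing values propagate;
#' non-positive values are an error.
#'
#' @param x positive values, \code{NA} allowed.
#' @return \code{log(x)}.
#' @export
log_transform <- function(x) {
  if (any(!is.na(x) & x <= 0)) stop("log_transform requires positive values")
  log(x)
}

#' Mardia's test of multivariate normality
#'
#' Multivariate skewness \eqn{b_{1,p}} and kurtosis \eqn{b_{2,p}} computed
#' from the squared Mahalanobis cross-products of the sample (covariance with
#' divisor n).  Reference distributions: \eqn{n b_{1,p} / 6} is
#' asymptotically chi-squared with \eqn{p(p+1)(p+2)/6} degrees of freedom;
#' \eqn{b_{2,p}} is asymptotically normal with mean \eqn{p(p+2)} and variance
#' \eqn{8 p (p+2) / n} (kurtosis p-value two-sided).
#'
#' @param x numeric matrix, rows = complete observations.
#' @return list of class \code{mardia_result}: \code{b1p}, \code{b2p},
#'   \code{skewness_stat} (the chi-squared deviate), \code{kurtosis_stat}
#'   (the normal deviate), \code{df_skewness}, \code{p_skewness},
#'   \code{p_kurtosis}, \code{n}, \code{p}.
#' @export
mardia_test <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("mardia_test requires complete rows")
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more observations than variables")
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n
  Si <- tryCatch(solve(S), error = function(e)
    stop("sample covariance is rank deficient"))
  D <- xc %*% Si %*% t(xc)          # n x n Mahalanobis cross-products
  b1p <- mean(D^3)
  b2p <- mean(diag(D)^2)
  df1 <- p * (p + 1) * (p + 2) / 6
  skew_stat <- n * b1p / 6
  kurt_stat <- (b2p - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  out <- list(b1p = b1p, b2p = b2p,
              skewness_stat = skew_stat, kurtosis_stat = kurt_stat,
              df_skewness = df1,
              p_skewness = stats::pchisq(skew_stat, df1, lower.tail = FALSE),
              p_kurtosis = 2 * stats::pnorm(-abs(kurt_stat)),
              n = n, p = p)
  class(out) <- "mardia_result"
  out
}

#' @export
print.mardia_result <- function(x, ...) {
  cat(sprintf("Mardia's test (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  skewness b1p = %.4f, chi2(%d) = %.3f, p = %.4f\n",
              x$b1p, x$df_skewness, x$skewness_stat, x$p_skewness))
  cat(sprintf("  kurtosis b2p = %.4f, z = %.3f, p = %.4f\n",
              x$b2p, x$kurtosis_stat, x$p_kurtosis))
  invisible(x)
}

#' Prepare the analysis-ready hormone phenotype of a cohort
#'
#' Applies, per individual-occasion row, the preprocessing pipeline:
#' creatinine correction per day (skipped for saliva hormones), two-day
#' combination honouring below-detection-limit flags, and natural-log
#' transform.  The result is stored in a new \code{hormone} column.  A child
#' below the detection limit on both days is missing (handled downstream by
#' full-information maximum likelihood); optionally the conventional
#' \code{limit / sqrt(2)} substitution can be applied per flagged day
#' instead.
#'
#' @param cohort a \code{twin_cohort} (see \code{\link{simulate_cohort}}) or
#'   a cohort data frame with columns \code{hormone_day1}, \code{hormone_day2},
#'   \code{creatinine_day1}, \code{creatinine_day2}, \code{below_limit_day1},
#'   \code{below_limit_day2}.
#' @param saliva if \code{TRUE}, skip the creatinine correction.
#' @param impute_below_limit if \code{TRUE}, flagged days enter as
#'   \code{detection_limit / sqrt(2)} (creatinine-corrected) instead of
#'   missing.  Off by default.
#' @param detection_limit assay floor on the raw scale; required when
#'   imputing.  Defaults to the cohort's configured limit when available.
#' @param column name of the output column.
#' @return the cohort with the prepared log-scale phenotype column added.
#' @export
prepare_hormone <- function(cohort, saliva = FALSE, impute_below_limit = FALSE,
                            detection_limit = NULL, column = "hormone") {
  d <- if (inherits(cohort, "twin_cohort")) cohort$data else cohort
  if (is.null(detection_limit) && inherits(cohort, "twin_cohort"))
    detection_limit <- cohort$detection_limit
  cr1 <- if (saliva) NULL else d$creatinine_day1
  cr2 <- if (saliva) NULL else d$creatinine_day2
  d1 <- normalize_creatinine(d$hormone_day1, cr1)
  d2 <- normalize_creatinine(d$hormone_day2, cr2)
  b1 <- d$below_limit_day1; b2 <- d$below_limit_day2
  if (impute_below_limit) {
    if (is.null(detection_limit))
      stop("impute_below_limit requires a detection_limit")
    imp1 <- normalize_creatinine(rep(detection_limit / sqrt(2), nrow(d)), cr1)
    imp2 <- normalize_creatinine(rep(detection_limit / sqrt(2), nrow(d)), cr2)
    d1[b1 %in% TRUE] <- imp1[b1 %in% TRUE]
    d2[b2 %in% TRUE] <- imp2[b2 %in% TRUE]
    b1 <- b2 <- FALSE
  }
  combined <- combine_days(d1, d2, b1, b2)
  d[[column]] <- log_transform(combined)
  if (inherits(cohort, "twin_cohort")) {
    cohort$data <- d
    cohort
  } else d
}

#' Below-detection-limit QC counts
#'
#' Tabulates, per occasion (and sex when present), how many subjects were
#' below the assay detection limit on 0, 1 or 2 of the sampling days.
#'
#' @param cohort a \code{twin_cohort} or cohort data frame.
#' @return data frame with columns \code{occasion}, (\code{sex}),
#'   \code{below_0_days}, \code{below_1_day}, \code{below_2_days}.
#' @export
hormone_qc <- function(cohort) {
  d <- if (inherits(cohort, "twin_cohort")) cohort$data else cohort
  nb <- (d$below_limit_day1 %in% TRUE) + (d$below_limit_day2 %in% TRUE)
  keys <- if ("sex" %in% names(d)) list(occasion = d$occasion, sex = d$sex)
          else list(occasion = d$occasion)
  agg <- stats::aggregate(nb, by = keys, FUN = function(v)
    c(sum(v == 0), sum(v == 1), sum(v == 2)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    below_0_days = agg$x[, 1],
                    below_1_day = agg$x[, 2],
                    below_2_days = agg$x[, 3])
  out[order(out$occasion), , drop = FALSE]
}
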