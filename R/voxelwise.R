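#' Voxel-wise longitudinal twin scan
#'
#' Mass-univariate driver: for every in-mask voxel, the four-phenotype
#' longitudinal model (hormone and that voxel's grey-matter density at ages 9
#' and 12) is fitted unconstrained and under the hypothesis constraint, and
#' the likelihood-ratio statistic plus the correlation decomposition are
#' recorded.  Hypotheses: \code{"change_corr"} constrains the correlation
#' between latent hormone change and latent density change to zero;
#' \code{"age12_cross_trait"} constrains the age-12 hormone-density
#' covariance to zero (both inside the same longitudinal model).
#'
#' Voxels are independent work units: each voxel's optimizer restarts are
#' seeded from \code{seed + voxel index}, so results do not depend on
#' processing order.  Voxels whose fits fail to converge are flagged, not
#' dropped.
#'
#' @param cohort a \code{twin_cohort} with prepared \code{hormone} column and
#'   voxel maps.
#' @param hypothesis \code{"change_corr"} or \code{"age12_cross_trait"}.
#' @param hormone name of the prepared hormone column.
#' @param mask logical vector over voxels (default: all).
#' @param sex optional stratum filter.
#' @param n_starts optimizer starts per voxel (default 1: the moment-based
#'   start, which is reliable at these problem sizes).
#' @param age_covariate correct the means for age at each measurement.
#' @param seed master seed for per-voxel restart seeds.
#' @param verbose log per-stage timing to stderr.
#' @return object of class \code{voxel_result_map}: \code{stats} data frame
#'   (one row per in-mask voxel: \code{voxel}, \code{r}, \code{chi2},
#'   \code{p}, \code{rph_a}, \code{rph_c}, \code{rph_e}, \code{converged}),
#'   \code{grid_shape}, \code{mask}, \code{hypothesis}, \code{thetas} (fitted
#'   full-model parameters, for warm-started follow-up fits).
#' @export
voxelwise_scan <- function(cohort, hypothesis = c("change_corr",
                                                  "age12_cross_trait"),
                           hormone = "hormone", mask = NULL, sex = NULL,
                           n_starts = 1, age_covariate = FALSE, seed = 1L,
                           verbose = FALSE) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(cohort$voxels)) stop("cohort has no voxel maps")
  nv <- prod(cohort$grid_shape)
  if (ncol(cohort$voxels) != nv)
    stop("voxel matrix does not match the grid shape (grid mismatch)")
  if (is.null(mask)) mask <- rep(TRUE, nv)
  if (length(mask) != nv) stop("mask does not match the grid (grid mismatch)")
  constraint <- if (hypothesis == "change_corr") "change_corr_zero"
                else "cross_trait_age12_zero"
  target <- if (hypothesis == "change_corr") "change" else "age12_cross_trait"

  ph <- twin_phenotypes(cohort, vars = c(hormone, "density"), sex = sex)
  dens_cols <- which(((seq_len(2 * ph$p) - 1) %% ph$p) %in% c(1, 3))
  t0 <- proc.time()[3]
  vox_idx <- which(mask)
  res <- vector("list", length(vox_idx))
  thetas <- vector("list", length(vox_idx))
  for (k in seq_along(vox_idx)) {
    v <- vox_idx[k]
    ph_v <- ph
    for (col in dens_cols) {
      rows <- which(!is.na(ph$row_index[, col]))
      ph_v$Y[rows, col] <- cohort$voxels[ph$row_index[rows, col], v]
    }
    vseed <- (seed + v) %% .Machine$integer.max
    out <- tryCatch({
      full <- fit_ace(ph_v, "none", target = target, n_starts = n_starts,
                      age_covariate = age_covariate, seed = vseed)
      con <- fit_ace(ph_v, constraint, target = target, n_starts = 1,
                     age_covariate = age_covariate, seed = vseed,
                     start = full$theta)
      test <- lrt(full, con)
      dec <- rph_decomposition(full$model, target = target)
      list(row = data.frame(voxel = v, r = dec$r, chi2 = test$chi2,
                            p = test$p, rph_a = dec$rph_a, rph_c = dec$rph_c,
                            rph_e = dec$rph_e,
                            converged = full$converged && con$converged),
           theta = full$theta)
    }, error = function(e) {
      list(row = data.frame(voxel = v, r = NA_real_, chi2 = NA_real_,
                            p = NA_real_, rph_a = NA_real_, rph_c = NA_real_,
                            rph_e = NA_real_, converged = FALSE),
           theta = NULL)
    })
    thetas[[k]] <- out$theta
    res[[k]] <- out$row
  }
  stats <- do.call(rbind, res)
  if (verbose)
    message(sprintf("scan: %d voxels in %.1f s", length(vox_idx),
                    proc.time()[3] - t0))
  out <- list(stats = stats, grid_shape = cohort$grid_shape, mask = mask,
              hypothesis = hypothesis, hormone = hormone, sex = sex,
              age_covariate = age_covariate, thetas = thetas, seed = seed,
              n_starts = n_starts)
  class(out) <- "voxel_result_map"
  out
}

#' @export
print.voxel_result_map <- function(x, ...) {
  cat(sprintf("voxel_result_map (%s): %d voxels, %d converged\n",
              x$hypothesis, nrow(x$stats), sum(x$stats$converged)))
  invisible(x)
}

#' Benjamini-Hochberg step-up false discovery rate threshold
#'
#' Sorts the p-values ascending and finds the largest k with
#' \code{p(k) <= k alpha / (m c)}; hypotheses 1..k are rejected.  The
#' constant is \code{c = 1} (the independence/PRDS form recommended for
#' imaging data); \code{conservative = TRUE} uses \code{c = sum(1/i)}
#' (arbitrary dependence).  The critical chi-squared value is the 1-df
#' upper-tail deviate at the largest rejected p.
#'
#' @param p_values p-values in [0, 1] (no missing values; exclude
#'   non-converged fits beforehand).
#' @param alpha FDR level.
#' @param conservative use the \code{c = sum(1/i)} variant.
#' @return object of class \code{fdr_result}: \code{alpha},
#'   \code{critical_p}, \code{critical_chi2}, \code{n_rejected},
#'   \code{mask} (logical, in input order), \code{m}.
#' @export
fdr_threshold <- function(p_values, alpha = 0.05, conservative = FALSE) {
  if (length(p_values) == 0) stop("p_values must be nonempty")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p_values must lie in [0, 1] with no missing values")
  m <- length(p_values)
  cv <- if (conservative) sum(1 / seq_len(m)) else 1
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * alpha / (m * cv))
  k <- if (length(ok)) max(ok) else 0L
  critical_p <- if (k > 0) ps[k] else NA_real_
  out <- list(alpha = alpha,
              critical_p = critical_p,
              critical_chi2 = if (k > 0)
                stats::qchisq(critical_p, df = 1, lower.tail = FALSE)
                else NA_real_,
              n_rejected = as.integer(k),
              mask = if (k > 0) p_values <= critical_p
                     else rep(FALSE, m),
              m = m, conservative = conservative)
  class(out) <- "fdr_result"
  out
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("FDR %.3g: %d / %d rejected; critical p = %.4g, critical chi2(1) = %.3f\n",
              x$alpha, x$n_rejected, x$m,
              if (is.na(x$critical_p)) NA else x$critical_p,
              if (is.na(x$critical_chi2)) NA else x$critical_chi2))
  invisible(x)
}

#' FDR correction of a voxel scan
#'
#' Applies \code{\link{fdr_threshold}} to the p-values of the converged
#' voxels of a scan (non-converged voxels are excluded from the pool, which
#' reduces m) and returns the result together with the rejected voxel
#' indices.
#'
#' @param map a \code{\link{voxelwise_scan}} result.
#' @param alpha FDR level.
#' @param conservative see \code{\link{fdr_threshold}}.
#' @return an \code{fdr_result} with extra fields \code{voxels} (pool) and
#'   \code{significant_voxels}.
#' @export
map_fdr <- function(map, alpha = 0.05, conservative = FALSE) {
  st <- map$stats
  pool <- st$converged & !is.na(st$p)
  fdr <- fdr_threshold(st$p[pool], alpha = alpha, conservative = conservative)
  fdr$voxels <- st$voxel[pool]
  fdr$significant_voxels <- st$voxel[pool][fdr$mask]
  fdr
}

# connected components of a logical 3-d array under 6-connectivity
connected_components_6 <- function(mask_array) {
  dims <- dim(mask_array)
  lab <- array(0L, dims)
  nextlab <- 0L
  idx <- which(mask_array)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, dims)
      for (d in seq_len(6)) {
        nb <- co + offs[d, ]
        if (any(nb < 1) || any(nb > dims)) next
        li <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (mask_array[li] && lab[li] == 0L) {
          lab[li] <- nextlab
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

#' Summaries and component attribution over significant voxels
#'
#' Mean correlation over the FDR-significant voxels; per-voxel
#' component-zeroing likelihood-ratio tests (genetic, common-environment,
#' unique-environment parts of the target covariance each constrained to
#' zero) with their own FDR pass restricted to the significant set; the
#' percentage of significant voxels attributable to each component (a voxel
#' where no single component reaches significance is "undetermined"); and a
#' listing of significant clusters by 6-connectivity.
#'
#' @param map a \code{\link{voxelwise_scan}} result.
#' @param fdr the matching \code{\link{map_fdr}} result.
#' @param cohort the cohort the scan was run on (needed to refit the
#'   component-zeroing models); if \code{NULL}, attribution is skipped.
#' @param alpha FDR level for the component tests.
#' @return list of class \code{voxel_summary}: \code{n_significant},
#'   \code{mean_r}, \code{pct_a}, \code{pct_c}, \code{pct_e},
#'   \code{pct_undetermined}, \code{component_critical_chi2} (per-component
#'   critical values), \code{attribution} (per-voxel data frame),
#'   \code{clusters} (data frame of connected components).
#' @export
summarize_significant <- function(map, fdr, cohort = NULL, alpha = 0.05) {
  sig <- fdr$significant_voxels
  st <- map$stats
  out <- list(n_significant = length(sig),
              mean_r = if (length(sig))
                mean(st$r[match(sig, st$voxel)]) else NA_real_,
              pct_a = NA_real_, pct_c = NA_real_, pct_e = NA_real_,
              pct_undetermined = NA_real_,
              component_critical_chi2 = c(a = NA_real_, c = NA_real_,
                                          e = NA_real_),
              attribution = NULL, clusters = NULL)
  class(out) <- "voxel_summary"
  # cluster listing
  arr <- array(FALSE, map$grid_shape)
  arr[sig] <- TRUE
  lab <- connected_components_6(arr)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    out$clusters <- data.frame(cluster = seq_along(sizes), n_voxels = sizes)
  } else {
    out$clusters <- data.frame(cluster = integer(0), n_voxels = integer(0))
  }
  if (length(sig) == 0 || is.null(cohort)) return(out)

  target <- if (map$hypothesis == "change_corr") "change"
            else "age12_cross_trait"
  ph <- twin_phenotypes(cohort, vars = c(map$hormone, "density"),
                        sex = map$sex)
  dens_cols <- which(((seq_len(2 * ph$p) - 1) %% ph$p) %in% c(1, 3))
  comps <- c("a", "c", "e")
  pv <- matrix(NA_real_, length(sig), 3, dimnames = list(NULL, comps))
  ch <- pv
  for (k in seq_along(sig)) {
    v <- sig[k]
    ph_v <- ph
    for (col in dens_cols) {
      rows <- which(!is.na(ph$row_index[, col]))
      ph_v$Y[rows, col] <- cohort$voxels[ph$row_index[rows, col], v]
    }
    warm <- map$thetas[[match(v, st$voxel)]]
    vseed <- (map$seed + v) %% .Machine$integer.max
    full <- fit_ace(ph_v, "none", target = target, n_starts = 1,
                    age_covariate = map$age_covariate, seed = vseed,
                    start = warm)
    for (j in seq_along(comps)) {
      conj <- tryCatch(
        fit_ace(ph_v, paste0("rph_", comps[j], "_zero"), target = target,
                n_starts = 1, age_covariate = map$age_covariate,
                seed = vseed, start = full$theta),
        error = function(e) NULL)
      if (!is.null(conj)) {
        tt <- lrt(full, conj)
        pv[k, j] <- tt$p; ch[k, j] <- tt$chi2
      }
    }
  }
  sig_mat <- matrix(FALSE, length(sig), 3, dimnames = list(NULL, comps))
  for (j in seq_along(comps)) {
    okj <- !is.na(pv[, j])
    if (!any(okj)) next
    fj <- fdr_threshold(pv[okj, j], alpha = alpha)
    sig_mat[okj, j] <- fj$mask
    out$component_critical_chi2[comps[j]] <-
      if (fj$n_rejected > 0)
        stats::qchisq(fj$critical_p, df = 1, lower.tail = FALSE)
      else NA_real_
  }
  out$pct_a <- 100 * mean(sig_mat[, "a"])
  out$pct_c <- 100 * mean(sig_mat[, "c"])
  out$pct_e <- 100 * mean(sig_mat[, "e"])
  out$pct_undetermined <- 100 * mean(rowSums(sig_mat) == 0)
  out$attribution <- data.frame(voxel = sig, p_a = pv[, "a"],
                                p_c = pv[, "c"], p_e = pv[, "e"],
                                chi2_a = ch[, "a"], chi2_c = ch[, "c"],
                                chi2_e = ch[, "e"],
                                sig_a = sig_mat[, "a"], sig_c = sig_mat[, "c"],
                                sig_e = sig_mat[, "e"])
  out
}

#' @export
print.voxel_summary <- function(x, ...) {
  cat(sprintf("%d significant voxels, mean r = %.3f\n", x$n_significant,
              x$mean_r))
  if (!is.na(x$pct_a))
    cat(sprintf("  driven by: A %.0f%%, C %.0f%%, E %.0f%%, undetermined %.0f%%\n",
                x$pct_a, x$pct_c, x$pct_e, x$pct_undetermined))
  if (!is.null(x$clusters) && nrow(x$clusters))
    cat(sprintf("  %d cluster(s), sizes: %s\n", nrow(x$clusters),
                paste(sort(x$clusters$n_voxels, decreasing = TRUE),
                      collapse = ", ")))
  invisible(x)
}

#' Write scan result maps to NIfTI with a JSON sidecar
#'
#' Volumes written: correlation, chi-squared, -log10(p), 0/1 significance
#' mask, and the three rph component maps; the sidecar records the FDR
#' result.
#'
#' @param map a \code{\link{voxelwise_scan}} result.
#' @param fdr the matching \code{\link{map_fdr}} result.
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_maps <- function(map, fdr, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- map$stats
  vol <- function(values, voxels) {
    a <- array(NA_real_, map$grid_shape)
    a[voxels] <- values
    a
  }
  files <- character(0)
  wr <- function(name, arr) {
    f <- file.path(out_dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(arr, f)
    files <<- c(files, f)
  }
  wr("r", vol(st$r, st$voxel))
  wr("chi2", vol(st$chi2, st$voxel))
  wr("neglog10p", vol(-log10(pmax(st$p, 1e-300)), st$voxel))
  msk <- array(0, map$grid_shape)
  msk[fdr$significant_voxels] <- 1
  wr("sig_mask", msk)
  wr("rph_a", vol(st$rph_a, st$voxel))
  wr("rph_c", vol(st$rph_c, st$voxel))
  wr("rph_e", vol(st$rph_e, st$voxel))
  side <- list(hypothesis = map$hypothesis, alpha = fdr$alpha,
               m = fdr$m, n_rejected = fdr$n_rejected,
               critical_p = fdr$critical_p,
               critical_chi2 = fdr$critical_chi2,
               n_nonconverged = sum(!st$converged),
               nonconverged_voxels = st$voxel[!st$converged])
  jf <- file.path(out_dir, "fdr.json")
  jsonlite::write_json(side, jf, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(files, jf))
}
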