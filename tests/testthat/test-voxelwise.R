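# brute-force step-up evaluation straight from the definition
bh_bruteforce <- function(p, alpha, cv = 1) {
  m <- length(p)
  ps <- sort(p)
  k_best <- 0
  for (k in seq_len(m)) if (ps[k] <= k * alpha / (m * cv)) k_best <- k
  list(k = k_best,
       critical_p = if (k_best > 0) ps[k_best] else NA_real_)
}

test_that("the step-up threshold matches brute-force evaluation", {
  r <- fdr_threshold(c(0.001, 0.01, 0.02, 0.8), alpha = 0.05)
  b <- bh_bruteforce(c(0.001, 0.01, 0.02, 0.8), 0.05)
  expect_equal(r$n_rejected, b$k)
  expect_equal(r$critical_p, b$critical_p)
  set.seed(61)
  for (i in 1:300) {
    m <- sample(1:50, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    a <- runif(1, 0.01, 0.2)
    cons <- runif(1) < 0.5
    r <- fdr_threshold(p, a, conservative = cons)
    b <- bh_bruteforce(p, a, if (cons) sum(1 / seq_len(m)) else 1)
    expect_equal(r$n_rejected, b$k)
    expect_equal(r$critical_p, b$critical_p)
    expect_equal(sum(r$mask), r$n_rejected)
    if (r$n_rejected > 0) {
      expect_true(all(p[r$mask] <= r$critical_p))
      expect_equal(r$critical_chi2,
                   qchisq(r$critical_p, 1, lower.tail = FALSE))
    }
  }
})

test_that("degenerate p-value vectors behave as defined", {
  all1 <- fdr_threshold(rep(1, 10))
  expect_equal(all1$n_rejected, 0L)
  expect_true(is.na(all1$critical_p))
  expect_false(any(all1$mask))
  all0 <- fdr_threshold(rep(0, 7))
  expect_equal(all0$n_rejected, 7L)
  expect_true(all(all0$mask))
  expect_error(fdr_threshold(numeric(0)), "nonempty")
  expect_error(fdr_threshold(c(0.1, NA)), "missing")
  expect_error(fdr_threshold(c(0.1, 1.2)), "0, 1")
})

test_that("rejections are monotone in alpha and the conservative variant rejects no more", {
  set.seed(62)
  for (i in 1:50) {
    p <- runif(sample(5:40, 1))^2
    r1 <- fdr_threshold(p, 0.01)
    r5 <- fdr_threshold(p, 0.05)
    expect_true(all(which(r1$mask) %in% which(r5$mask)))
    rc <- fdr_threshold(p, 0.05, conservative = TRUE)
    expect_lte(rc$n_rejected, r5$n_rejected)
  }
})

test_that("a single-voxel scan equals a direct fit and likelihood-ratio test", {
  co <- tiny_cohort(seed = 63, n_mz = 80, n_dz = 80, grid = c(1, 1, 1))
  m <- voxelwise_scan(co, "change_corr", seed = 17)
  expect_equal(nrow(m$stats), 1)
  # with a single-voxel grid inside the cluster, the voxel map equals the
  # scalar density phenotype, so a direct fit must reproduce the scan
  ph <- twin_phenotypes(co)
  full <- fit_ace(ph, n_starts = 1, seed = (17 + 1) %% .Machine$integer.max)
  con <- fit_ace(ph, "change_corr_zero", n_starts = 1, start = full$theta,
                 seed = (17 + 1) %% .Machine$integer.max)
  t <- lrt(full, con)
  expect_equal(m$stats$chi2, t$chi2, tolerance = 1e-6)
  expect_equal(m$stats$r, rph_decomposition(full$model)$r, tolerance = 1e-6)
})

test_that("the scan is invariant to voxel processing order", {
  co <- tiny_cohort(seed = 64, n_mz = 60, n_dz = 60, grid = c(2, 2, 1))
  m1 <- voxelwise_scan(co, "change_corr", seed = 3)
  mask <- rep(TRUE, 4)
  # processing a subset reproduces the same per-voxel results
  m2 <- voxelwise_scan(co, "change_corr", seed = 3,
                       mask = c(FALSE, TRUE, TRUE, FALSE))
  sub <- m1$stats[m1$stats$voxel %in% 2:3, ]
  rownames(sub) <- NULL
  expect_equal(m2$stats, sub)
})

test_that("grid mismatches are rejected", {
  co <- tiny_cohort(seed = 65, n_mz = 10, n_dz = 10, grid = c(2, 2, 1))
  co$grid_shape <- c(3, 3, 1)
  expect_error(voxelwise_scan(co, "change_corr"), "grid mismatch")
  co <- tiny_cohort(seed = 65, n_mz = 10, n_dz = 10, grid = c(2, 2, 1))
  expect_error(voxelwise_scan(co, "change_corr", mask = rep(TRUE, 3)),
               "grid mismatch")
})

test_that("connected components follow 6-connectivity", {
  a <- array(FALSE, c(4, 4, 2))
  a[1:2, 1, 1] <- TRUE          # cluster of 2
  a[4, 4, 2] <- TRUE            # isolated voxel
  a[4, 4, 1] <- TRUE            # face-adjacent to the isolated voxel
  a[1, 4, 1] <- TRUE            # diagonal neighbours do NOT connect
  lab <- pubertwin:::connected_components_6(a)
  expect_equal(max(lab), 3)
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sizes, c(1, 2, 2))
})

test_that("summaries, attribution and written maps are internally consistent", {
  co <- tiny_cohort(seed = 66, n_mz = 150, n_dz = 150, grid = c(3, 3, 1),
                    cluster_size = 1)
  map <- voxelwise_scan(co, "change_corr", seed = 19)
  fdr <- map_fdr(map, alpha = 0.05)
  sm <- summarize_significant(map, fdr, co)
  expect_equal(sm$n_significant, fdr$n_rejected)
  if (sm$n_significant == 1) {
    v <- fdr$significant_voxels[1]
    expect_equal(sm$mean_r, map$stats$r[map$stats$voxel == v])
  } else if (sm$n_significant > 1) {
    expect_equal(sm$mean_r,
                 mean(map$stats$r[map$stats$voxel %in%
                                    fdr$significant_voxels]))
  }
  dir <- withr::local_tempdir()
  files <- write_maps(map, fdr, dir)
  msk <- RNifti::readNifti(file.path(dir, "sig_mask.nii.gz"))
  expect_true(all(msk %in% c(0, 1)))
  side <- jsonlite::read_json(file.path(dir, "fdr.json"),
                              simplifyVector = TRUE)
  expect_equal(side$n_rejected, sum(msk))
  rmap <- RNifti::readNifti(file.path(dir, "r.nii.gz"))
  expect_equal(as.vector(rmap)[map$stats$voxel], map$stats$r,
               tolerance = 1e-6)
})

test_that("an all-null map yields an empty summary", {
  co <- tiny_cohort(seed = 67, n_mz = 80, n_dz = 80, grid = c(2, 2, 1),
                    coupling = "none")
  map <- voxelwise_scan(co, "change_corr", seed = 23)
  fdr <- map_fdr(map, alpha = 0.01)
  if (fdr$n_rejected == 0) {
    sm <- summarize_significant(map, fdr, co)
    expect_equal(sm$n_significant, 0)
    expect_true(is.na(sm$mean_r))
    expect_equal(nrow(sm$clusters), 0)
  } else succeed("chance rejection under the null; covered elsewhere")
})

test_that("the age-12 cross-trait hypothesis is exercised by the scan", {
  co <- tiny_cohort(seed = 68, n_mz = 120, n_dz = 120, grid = c(1, 1, 1))
  map <- voxelwise_scan(co, "age12_cross_trait", seed = 29)
  expect_true(map$stats$converged)
  expect_true(map$stats$p >= 0 && map$stats$p <= 1)
  # true age-12 cross-trait correlation is e3 re34 e4 = 0.18 > 0
  expect_gt(map$stats$r, 0)
})
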