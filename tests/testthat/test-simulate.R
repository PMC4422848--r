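twin_cor <- function(cohort, zyg, column = "density", occ = 1) {
  d <- cohort$data
  d <- d[d$zygosity == zyg & d$occasion == occ, ]
  t1 <- d[d$twin_id == 1, c("family_id", column)]
  t2 <- d[d$twin_id == 2, c("family_id", column)]
  mg <- merge(t1, t2, by = "family_id")
  cor(mg[[paste0(column, ".x")]], mg[[paste0(column, ".y")]])
}

sim_cfg <- function(model, n = 2000, seed = 5, ...) {
  simulation_config(n_mz_pairs = n, n_dz_pairs = n, n_mz_singletons = 0,
                    n_dz_singletons = 0, path_model = model,
                    grid_shape = c(1, 1, 1),
                    signal_cluster = central_cluster(c(1, 1, 1), 1),
                    smoothing_fwhm_voxels = 0, dropout_rate_occasion2 = 0,
                    rng_seed = seed, ...)
}

test_that("identical configs and seeds give identical cohorts", {
  cfg <- simulation_config(n_mz_pairs = 10, n_dz_pairs = 10,
                           grid_shape = c(3, 3, 3),
                           signal_cluster = central_cluster(c(3, 3, 3), 1),
                           rng_seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$voxels, b$voxels)
})

test_that("twin correlations follow the ACE variance shares", {
  # no familial factors: both twin correlations near zero
  m0 <- path_model(a = rep(0, 4), c = rep(0, 4), e = rep(1, 4))
  co <- simulate_cohort(sim_cfg(m0, seed = 8))
  expect_lt(abs(twin_cor(co, "MZ")), 0.05)
  expect_lt(abs(twin_cor(co, "DZ")), 0.05)
  # a2 = 0.6, c2 = 0.2, e2 = 0.2: rMZ = a2 + c2, rDZ = a2/2 + c2
  m1 <- path_model(a = rep(sqrt(0.6), 4), c = rep(sqrt(0.2), 4),
                   e = rep(sqrt(0.2), 4))
  co1 <- simulate_cohort(sim_cfg(m1, seed = 9))
  expect_lt(abs(twin_cor(co1, "MZ") - 0.8), 0.04)
  expect_lt(abs(twin_cor(co1, "DZ") - 0.5), 0.04)
})

test_that("common-environment factors are shared exactly within pairs", {
  # c-dominated model: twins should be near-duplicates in both zygosities
  m <- path_model(a = rep(0, 4), c = rep(1, 4), e = rep(0.02, 4))
  co <- simulate_cohort(sim_cfg(m, n = 300, seed = 10))
  expect_gt(twin_cor(co, "MZ"), 0.999)
  expect_gt(twin_cor(co, "DZ"), 0.999)
})

test_that("observed covariance of a large cohort matches the model-implied covariance", {
  m <- default_path_model()
  co <- simulate_cohort(sim_cfg(m, n = 3000, seed = 11))
  # the scalar density phenotype carries no assay noise, so its observed
  # longitudinal covariance estimates the (2, 4) block of expected_cov
  d <- co$data
  for (z in c("MZ", "DZ")) {
    dd <- d[d$zygosity == z, ]
    key <- paste(dd$family_id, dd$twin_id)
    ids <- unique(key)
    M <- matrix(NA_real_, length(ids), 2)
    M[cbind(match(key, ids), dd$occasion)] <- dd$density
    S <- cov(M)
    Sm <- expected_cov(m, z)[c(2, 4), c(2, 4)]
    se <- sqrt((diag(Sm) %o% diag(Sm) + Sm^2) / length(ids))
    expect_lt(max(abs(S - Sm) / se), 4)
  }
})

test_that("occasion-2 dropout matches its configured rate", {
  cfg <- sim_cfg(default_path_model(), n = 1500, seed = 12)
  cfg$dropout_rate_occasion2 <- 0.3
  co <- simulate_cohort(cfg)
  n_ind <- length(unique(paste(co$data$family_id, co$data$twin_id)))
  n_ret <- sum(co$data$occasion == 2)
  ci <- qbinom(c(0.0005, 0.9995), n_ind, 0.7)
  expect_gte(n_ret, ci[1])
  expect_lte(n_ret, ci[2])
})

test_that("signal-cluster voxels carry the coupled density and others do not", {
  cfg <- simulation_config(n_mz_pairs = 400, n_dz_pairs = 400,
                           n_mz_singletons = 0, n_dz_singletons = 0,
                           grid_shape = c(4, 4, 4),
                           signal_cluster = central_cluster(c(4, 4, 4), 2),
                           smoothing_fwhm_voxels = 1.5,
                           dropout_rate_occasion2 = 0, rng_seed = 13)
  co <- prepare_hormone(simulate_cohort(cfg))
  d <- co$data
  o2 <- d$occasion == 2
  h <- d$hormone[o2]
  incl <- co$signal_cluster[1]
  outv <- setdiff(seq_len(prod(co$grid_shape)), co$signal_cluster)[1]
  r_in <- cor(h, co$voxels[o2, incl], use = "complete.obs")
  r_out <- cor(h, co$voxels[o2, outv], use = "complete.obs")
  # truth: within-person hormone-density correlation at age 12 is
  # e3 re34 e4 = 0.18 inside the cluster, 0 outside
  expect_gt(r_in, 0.08)
  expect_lt(abs(r_out), 0.08)
  # cluster voxels equal the scalar density phenotype
  expect_equal(co$voxels[, incl], d$density)
})

test_that("cohorts round-trip through disk including missingness and grid", {
  co <- tiny_cohort(seed = 21, n_mz = 15, n_dz = 15, grid = c(3, 2, 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$grid_shape, co$grid_shape)
  expect_equal(back$signal_cluster, co$signal_cluster)
  num <- vapply(co$data, is.numeric, logical(1))
  for (cn in names(co$data)[num])
    expect_equal(back$data[[cn]], co$data[[cn]], tolerance = 1e-12)
  expect_identical(back$data$below_limit_day1, co$data$below_limit_day1)
  expect_true(any(is.na(back$data$hormone_day1)) ==
                any(is.na(co$data$hormone_day1)))
  expect_equal(back$voxels, co$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  # header grid of a written map matches the configured grid
  f <- file.path(dir, back$data$voxel_map_path[1])
  expect_equal(dim(RNifti::readNifti(f)), co$grid_shape)
})
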