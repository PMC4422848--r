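test_that("FIML equals the complete-data likelihood when nothing is missing", {
  set.seed(101)
  m <- random_path_model(4, seed = 7)
  Y <- draw_pairs(m, "MZ", 40)
  Y2 <- draw_pairs(m, "DZ", 40)
  ph <- manual_ph(rbind(Y, Y2), rep(c("MZ", "DZ"), each = 40), 4)
  ll <- fiml_loglik(m, ph)
  direct <- 0
  mu <- rep(m$means, 2)
  for (i in 1:80) {
    S <- expected_cov(m, ph$families$zygosity[i])
    direct <- direct + mvn_logdens(ph$Y[i, ], mu, S)
  }
  expect_equal(ll, direct, tolerance = 1e-9)
})

test_that("a family with one observed value contributes the univariate density", {
  m <- random_path_model(4, seed = 8)
  Y <- matrix(NA_real_, 1, 8)
  y <- 0.83
  Y[1, 3] <- y
  ph <- manual_ph(Y, "DZ", 4)
  v <- expected_cov(m, "DZ")[3, 3]
  mm <- m$means[3]
  expect_equal(fiml_loglik(m, ph),
               -0.5 * (log(2 * pi * v) + (y - mm)^2 / v), tolerance = 1e-12)
})

test_that("missing phenotypes are marginalized exactly", {
  set.seed(102)
  m <- random_path_model(4, seed = 9)
  y <- draw_pairs(m, "MZ", 1)[1, ]
  drop_idx <- c(2, 7)
  Y <- matrix(y, 1, 8)
  Y[1, drop_idx] <- NA
  ph <- manual_ph(Y, "MZ", 4)
  S <- expected_cov(m, "MZ")
  obs <- setdiff(1:8, drop_idx)
  expect_equal(fiml_loglik(m, ph),
               mvn_logdens(y[obs], rep(m$means, 2)[obs],
                           S[obs, obs, drop = FALSE]),
               tolerance = 1e-9)
})

test_that("the likelihood is invariant to family order and twin labeling", {
  co <- tiny_cohort(seed = 41, n_mz = 30, n_dz = 30)
  ph <- twin_phenotypes(co)
  m <- co$truth
  ll <- fiml_loglik(m, ph)
  perm <- sample(nrow(ph$Y))
  ph2 <- ph
  ph2$Y <- ph$Y[perm, ]; ph2$age <- ph$age[perm, ]
  ph2$families <- ph$families[perm, ]
  expect_equal(fiml_loglik(m, ph2), ll, tolerance = 1e-10)
  ph3 <- ph
  ph3$Y <- ph$Y[, c(5:8, 1:4)]   # swap twin 1 and twin 2
  expect_equal(fiml_loglik(m, ph3), ll, tolerance = 1e-10)
})

test_that("a singular observed submatrix is reported with the family", {
  Re <- matrix(1, 2, 2)
  m <- path_model(a = c(0, 0), c = c(0, 0), e = c(1, 1), R_e = Re)
  Y <- matrix(c(0.5, 0.7, NA, NA), 1, 4)
  ph <- manual_ph(Y, "MZ", 2)
  expect_error(fiml_loglik(m, ph), "f0001")
})

test_that("the compiled objective and gradient match the R likelihood and finite differences", {
  co <- tiny_cohort(seed = 42, n_mz = 40, n_dz = 40)
  ph <- twin_phenotypes(co)
  for (age in c(FALSE, TRUE)) {
    gr <- pubertwin:::build_groups(ph, age)
    th <- pubertwin:::moment_start(ph, age)
    nll <- pubertwin:::fiml_nll_groups(th, 4, gr, age)
    model <- pubertwin:::theta_to_model(th, 4)
    if (age) model$age_slopes <- th[(length(th) - 3):length(th)]
    expect_equal(-nll, fiml_loglik(model, ph, age_covariate = age),
                 tolerance = 1e-8)
    g <- pubertwin:::fiml_grad_groups(th, 4, gr, age)
    fd <- vapply(seq_along(th), function(k) {
      h <- 1e-6; tp <- th; tm <- th
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (pubertwin:::fiml_nll_groups(tp, 4, gr, age) -
         pubertwin:::fiml_nll_groups(tm, 4, gr, age)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / (1 + abs(fd))), 1e-4)
  }
})

test_that("constrained fits never beat the unconstrained likelihood and satisfy their constraint", {
  co <- tiny_cohort(seed = 43, n_mz = 80, n_dz = 80)
  ph <- twin_phenotypes(co)
  full <- fit_ace(ph, n_starts = 2)
  expect_true(full$converged)
  for (cons in c("change_corr_zero", "cross_trait_age12_zero",
                 "rph_e_zero")) {
    fc <- fit_ace(ph, cons, n_starts = 1, start = full$theta)
    expect_true(fc$converged)
    expect_lte(fc$loglik, full$loglik + 1e-6)
    expect_lt(abs(fc$constraint_value), 1e-7)
    t <- lrt(full, fc)
    expect_equal(t$df, 1)
    expect_gte(t$chi2, 0)
  }
})

test_that("likelihood-ratio arithmetic matches the chi-squared reference", {
  a <- structure(list(loglik = -100, n_params = 34), class = "ace_fit")
  b <- structure(list(loglik = -100, n_params = 33), class = "ace_fit")
  t0 <- lrt(a, b)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  b$loglik <- -100 - 3.841459 / 2
  t1 <- lrt(a, b)
  expect_equal(t1$p, 0.05, tolerance = 1e-4)
  expect_error(lrt(b, a), "fewer free parameters")
})

test_that("parameters are recovered from simulated cohorts", {
  co <- tiny_cohort(seed = 44, n_mz = 300, n_dz = 300, dropout = 0.2)
  fit <- fit_ace(twin_phenotypes(co), n_starts = 2)
  expect_true(fit$converged)
  truth <- co$truth
  # single-replicate smoke check: mean absolute error across phenotypes
  # (per-phenotype estimates of a variance share at this n have SE ~ 0.1)
  expect_lt(mean(abs(fit$model$a^2 - truth$a^2)), 0.15)
  expect_lt(mean(abs(fit$model$c^2 - truth$c^2)), 0.15)
  expect_lt(mean(abs(fit$model$e^2 - truth$e^2)), 0.15)
  d <- rph_decomposition(fit$model)
  expect_lt(abs(d$r - rph_decomposition(truth)$r), 0.15)
  # likelihood at the truth cannot beat the maximized likelihood
  expect_gte(fit$loglik + 1e-6, fiml_loglik(truth, twin_phenotypes(co)))
})

test_that("the bivariate age-12 model equals the longitudinal model with occasion 1 removed", {
  co <- tiny_cohort(seed = 45, n_mz = 120, n_dz = 120)
  ph4 <- twin_phenotypes(co)
  ph4$Y[, c(1, 2, 5, 6)] <- NA     # blank out all age-9 phenotypes
  f4 <- fit_ace(ph4, n_starts = 2)
  f2 <- fit_bivariate_age12(co, n_starts = 2)
  expect_true(f2$converged)
  # the age-9 submodel is unidentified/empty; compare the age-12 part
  expect_equal(f2$loglik, f4$loglik, tolerance = 1e-4)
  d2 <- rph_decomposition(f2$model, "age12_cross_trait")
  expect_true(abs(d2$r) <= 1)
})

test_that("age-covariate fits recover a mean age trend", {
  co <- tiny_cohort(seed = 46, n_mz = 150, n_dz = 150)
  # inject a strong age trend into the density phenotype
  co$data$density <- co$data$density + 0.8 * co$data$age
  ph <- twin_phenotypes(co)
  fit <- fit_ace(ph, n_starts = 1, age_covariate = TRUE)
  plain <- fit_ace(ph, n_starts = 1)
  expect_true(fit$converged)
  # age spread within an occasion is small (sd ~0.1-0.25 y), so slopes are
  # noisy; check sign/magnitude and that modeling age pays off in likelihood
  expect_gt(min(fit$model$age_slopes[c(2, 4)]), 0.2)
  expect_gt(fit$loglik, plain$loglik)
})
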