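# small cohorts and fixtures built in code; no stored data

tiny_cohort <- function(seed = 1, n_mz = 60, n_dz = 60, coupling = "e",
                        grid = c(2, 2, 2), cluster_size = 1,
                        dropout = 0.2, ...) {
  cfg <- simulation_config(
    n_mz_pairs = n_mz, n_dz_pairs = n_dz,
    n_mz_singletons = 0, n_dz_singletons = 0,
    path_model = default_path_model(coupling = coupling),
    grid_shape = grid,
    signal_cluster = central_cluster(grid, cluster_size),
    smoothing_fwhm_voxels = 0,
    dropout_rate_occasion2 = dropout,
    rng_seed = seed, ...)
  prepare_hormone(simulate_cohort(cfg))
}

# generative factor-model draws for a pair (independent oracle for
# expected_cov: never goes through expected_cov itself)
draw_pairs <- function(model, zygosity, n) {
  p <- length(model$a)
  rz <- if (zygosity == "MZ") 1 else 0.5
  Lg <- t(chol(model$R_g + diag(1e-10, p)))
  Lc <- t(chol(model$R_c + diag(1e-10, p)))
  Le <- t(chol(model$R_e + diag(1e-10, p)))
  Z1 <- matrix(rnorm(n * p), n, p); Z2 <- matrix(rnorm(n * p), n, p)
  A1 <- Z1 %*% t(Lg)
  A2 <- (rz * Z1 + sqrt(1 - rz^2) * Z2) %*% t(Lg)
  Cc <- matrix(rnorm(n * p), n, p) %*% t(Lc)
  E1 <- matrix(rnorm(n * p), n, p) %*% t(Le)
  E2 <- matrix(rnorm(n * p), n, p) %*% t(Le)
  sweep1 <- function(A, C, E)
    sweep(A %*% diag(model$a) + C %*% diag(model$c) + E %*% diag(model$e),
          2, model$means, "+")
  cbind(sweep1(A1, Cc, E1), sweep1(A2, Cc, E2))
}

# hand-rolled multivariate-normal log density via solve/determinant,
# an implementation independent of the package's Cholesky-based code
mvn_logdens <- function(y, mu, S) {
  k <- length(y)
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            drop(t(y - mu) %*% solve(S) %*% (y - mu)))
}

# wide phenotype structure built directly from matrices (bypasses cohorts)
manual_ph <- function(Y, zygosity, p) {
  n <- nrow(Y)
  fams <- data.frame(family_id = sprintf("f%04d", seq_len(n)),
                     zygosity = zygosity)
  structure(list(Y = Y, age = matrix(NA_real_, n, 2 * p),
                 age_centers = c(0, 0), families = fams, p = p,
                 labels = paste0("ph", seq_len(p)),
                 row_index = matrix(NA_integer_, n, 2 * p),
                 vars = NULL, occasions = NULL),
            class = "twin_phenotypes")
}
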