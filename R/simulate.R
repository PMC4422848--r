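#' Default ground-truth path model for simulated cohorts
#'
#' A four-phenotype model with variance shares typical of pubertal hormone
#' and grey-matter density phenotypes in late childhood: a2 = 0.5, c2 = 0.2,
#' e2 = 0.3 for every phenotype, strong longitudinal stability of the genetic
#' (0.8) and common-environment (0.9) factors, weak stability of the unique
#' environment (0.2), and a hormone-density coupling carried by a single
#' factor kind.  With the default unique-environment coupling of 0.6 at both
#' ages, the implied correlation between latent hormone change and latent
#' density change is 0.5.
#'
#' @param coupling which factor kind links hormone and density:
#'   \code{"e"} (unique environment), \code{"c"} (common environment, applied
#'   at both ages with the separable longitudinal structure), or
#'   \code{"none"}.
#' @param coupling_strength cross-trait factor correlation (default 0.6).
#' @param means phenotype means; the default puts the hormone on a log scale
#'   resembling creatinine-corrected FSH (U/mmol) in girls at ages 9 and 12.
#' @return a \code{\link{path_model}}.
#' @export
default_path_model <- function(coupling = c("e", "c", "none"),
                               coupling_strength = 0.6,
                               means = c(-0.75, 0, -0.08, 0)) {
  coupling <- match.arg(coupling)
  rho <- coupling_strength
  long_cor <- function(l, x12 = 0, x14 = 0) {
    # phenotypes (h9, d9, h12, d12); l = within-trait age-9/age-12 correlation
    R <- diag(4)
    R[1, 3] <- R[3, 1] <- l
    R[2, 4] <- R[4, 2] <- l
    R[1, 2] <- R[2, 1] <- x12
    R[3, 4] <- R[4, 3] <- x12
    R[1, 4] <- R[4, 1] <- x14
    R[2, 3] <- R[3, 2] <- x14
    R
  }
  R_g <- long_cor(0.8)
  R_c <- long_cor(0.9)
  R_e <- long_cor(0.2)
  if (coupling == "e") {
    R_e <- long_cor(0.2, x12 = rho)
  } else if (coupling == "c") {
    # separable trait x age structure keeps the matrix positive definite
    R_c <- long_cor(0.9, x12 = rho, x14 = rho * 0.9)
  }
  path_model(a = rep(sqrt(0.5), 4), c = rep(sqrt(0.2), 4),
             e = rep(sqrt(0.3), 4), R_g = R_g, R_c = R_c, R_e = R_e,
             means = means)
}

#' Linear voxel indices of a centred cubic cluster
#'
#' @param grid_shape 3 integers.
#' @param size cube edge length in voxels.
#' @return integer vector of column-major linear indices.
#' @export
central_cluster <- function(grid_shape, size = 3) {
  stopifnot(length(grid_shape) == 3, all(size <= grid_shape))
  rng <- lapply(grid_shape, function(L) {
    s <- floor((L - size) / 2) + 1
    s:(s + size - 1)
  })
  g <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
  sort(g[[1]] + (g[[2]] - 1) * grid_shape[1] +
         (g[[3]] - 1) * grid_shape[1] * grid_shape[2])
}

#' Configuration of a synthetic twin cohort
#'
#' Defaults emulate the female stratum of a two-occasion twin-MRI study of
#' about 190 nine-year-olds of whom about two thirds return at age 12:
#' 21 complete MZ pairs and 16 complete DZ pairs plus singleton members of
#' incomplete or opposite-sex pairs, 34 percent occasion-2 dropout
#' (missing completely at random), a log-normal observed hormone scale with
#' an assay detection limit, two sampling days per occasion, and spatially
#' smooth voxel maps carrying a localized true hormone-density coupling.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of complete same-sex pairs.
#' @param n_mz_singletons,n_dz_singletons individuals entered as incomplete
#'   pairs (e.g. members of opposite-sex pairs in a sex-stratified analysis).
#' @param path_model ground-truth \code{\link{path_model}} (4 phenotypes).
#' @param phenotype_means optional override of the model means.
#' @param grid_shape 3 integers, voxel grid.
#' @param signal_cluster linear voxel indices carrying the hormone-density
#'   coupling; default a centred 3x3x3 cube.
#' @param smoothing_fwhm_voxels Gaussian smoothing FWHM (voxels) of the
#'   unique-environment voxel field.
#' @param dropout_rate_occasion2 fraction in [0, 1] of individuals missing
#'   the entire second occasion.
#' @param detection_limit assay floor on the raw (pre-creatinine-correction)
#'   scale.
#' @param assay_sd standard deviation of per-day log-scale assay noise.
#' @param creatinine_meanlog,creatinine_sdlog log-normal parameters of the
#'   per-day urinary creatinine concentration (mmol/l).
#' @param sex stratum label stored in the table.
#' @param rng_seed integer seed; mandatory for reproducibility.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_mz_pairs = 21, n_dz_pairs = 16,
                              n_mz_singletons = 1, n_dz_singletons = 24,
                              path_model = default_path_model(),
                              phenotype_means = NULL,
                              grid_shape = c(10, 10, 10),
                              signal_cluster = central_cluster(grid_shape),
                              smoothing_fwhm_voxels = 3,
                              dropout_rate_occasion2 = 1 - 125 / 190,
                              detection_limit = 0.11,
                              assay_sd = 0.2,
                              creatinine_meanlog = log(8),
                              creatinine_sdlog = 0.4,
                              sex = "F",
                              rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  if (!is.null(phenotype_means)) path_model$means <- as.numeric(phenotype_means)
  validate_path_model(path_model)
  if (length(path_model$a) != 4) stop("the generator needs a 4-phenotype model")
  cfg <- list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              n_mz_singletons = n_mz_singletons,
              n_dz_singletons = n_dz_singletons,
              path_model = path_model, grid_shape = as.integer(grid_shape),
              signal_cluster = as.integer(signal_cluster),
              smoothing_fwhm_voxels = smoothing_fwhm_voxels,
              dropout_rate_occasion2 = dropout_rate_occasion2,
              detection_limit = detection_limit, assay_sd = assay_sd,
              creatinine_meanlog = creatinine_meanlog,
              creatinine_sdlog = creatinine_sdlog, sex = sex,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  counts <- c(cfg$n_mz_pairs, cfg$n_dz_pairs, cfg$n_mz_singletons,
              cfg$n_dz_singletons)
  if (any(counts < 0)) stop("pair/singleton counts must be >= 0")
  if (cfg$dropout_rate_occasion2 < 0 || cfg$dropout_rate_occasion2 > 1)
    stop("dropout_rate_occasion2 must lie in [0, 1]")
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 1))
    stop("grid_shape must be 3 positive integers")
  nv <- prod(cfg$grid_shape)
  if (length(cfg$signal_cluster) &&
      (min(cfg$signal_cluster) < 1 || max(cfg$signal_cluster) > nv))
    stop("signal_cluster must index voxels inside the grid")
  if (cfg$smoothing_fwhm_voxels < 0) stop("smoothing FWHM must be >= 0")
  invisible(TRUE)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields of \code{\link{simulation_config}} can be set in the file;
#' \code{rng_seed} is mandatory.  \code{path_model_coupling} and
#' \code{path_model_coupling_strength} select a \code{\link{default_path_model}}
#' variant.
#'
#' @param path YAML file.
#' @return a \code{simulation_config}.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$rng_seed)) stop("config file must set rng_seed")
  pm <- default_path_model(
    coupling = if (is.null(y$path_model_coupling)) "e" else y$path_model_coupling,
    coupling_strength = if (is.null(y$path_model_coupling_strength)) 0.6
                        else y$path_model_coupling_strength)
  y$path_model_coupling <- NULL
  y$path_model_coupling_strength <- NULL
  args <- y[intersect(names(y), names(formals(simulation_config)))]
  args$path_model <- pm
  if (!is.null(args$grid_shape))
    args$signal_cluster <- central_cluster(as.integer(args$grid_shape))
  do.call(simulation_config, args)
}

# n independent unit-variance Gaussian random fields on a 3-d torus,
# smoothed by circular convolution with an isotropic Gaussian kernel
gaussian_fields <- function(n, grid_shape, fwhm) {
  nv <- prod(grid_shape)
  W <- matrix(stats::rnorm(n * nv), n, nv)
  if (fwhm <= 0 || n == 0) return(W)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  ks <- lapply(grid_shape, function(L) {
    d <- pmin(0:(L - 1), L - (0:(L - 1)))
    exp(-d^2 / (2 * sigma^2))
  })
  kernel <- array(outer(outer(ks[[1]], ks[[2]]), ks[[3]]), dim = grid_shape)
  Kf <- stats::fft(kernel)
  nrm <- sqrt(sum(kernel^2))
  for (i in seq_len(n)) {
    sm <- Re(stats::fft(stats::fft(array(W[i, ], grid_shape)) * Kf,
                        inverse = TRUE)) / nv
    W[i, ] <- as.vector(sm) / nrm
  }
  W
}

#' Simulate a twin cohort from the generative factor model
#'
#' Per pair, additive-genetic factors are drawn with cross-twin correlation 1
#' (MZ) or 0.5 (DZ), common-environment factors are shared exactly within the
#' pair, and unique-environment factors are independent per individual;
#' phenotypes are \code{mean + a A + c C + e E}.  The hormone is observed on
#' two sampling days per occasion as
#' \code{exp(latent + assay noise) * creatinine} (so the observed scale is
#' log-normal), censored at the detection limit.  Voxel maps replicate the
#' density phenotype over the grid: inside the signal cluster the coupling
#' paths of the ground-truth model are active (cluster voxels share the
#' coupled density value); outside, density is generated from the same
#' marginal model with all hormone-density cross-correlations removed, with
#' genetic and common-environment factors drawn independently per voxel and
#' a spatially smooth unique-environment field (only the unique-environment
#' part carries spatial correlation).  The entire second occasion of an
#' individual is dropped with the configured probability (missing completely
#' at random).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return an object of class \code{twin_cohort}: list with \code{data} (one
#'   row per individual-occasion), \code{voxels} (matrix, rows aligned with
#'   \code{data}), \code{grid_shape}, \code{signal_cluster},
#'   \code{detection_limit}, \code{phenotypes}, \code{occasions}, and the
#'   ground-truth \code{truth} model.
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$rng_seed)
  model <- config$path_model
  p <- 4
  mu <- model$means
  comp <- ace_components(model)
  Lg <- t(chol(model$R_g + diag(1e-10, p)))
  Lc <- t(chol(model$R_c + diag(1e-10, p)))
  Le <- t(chol(model$R_e + diag(1e-10, p)))
  # uncoupled marginal density model for voxels outside the signal cluster
  dens <- c(2, 4)
  Rg2 <- model$R_g[dens, dens]; Rc2 <- model$R_c[dens, dens]
  Re2 <- model$R_e[dens, dens]
  Lg2 <- t(chol(Rg2 + diag(1e-10, 2)))
  Lc2 <- t(chol(Rc2 + diag(1e-10, 2)))
  re_age <- Re2[1, 2]

  zyg <- c(rep("MZ", config$n_mz_pairs), rep("DZ", config$n_dz_pairs),
           rep("MZ", config$n_mz_singletons), rep("DZ", config$n_dz_singletons))
  n_members <- c(rep(2L, config$n_mz_pairs + config$n_dz_pairs),
                 rep(1L, config$n_mz_singletons + config$n_dz_singletons))
  n_pairs <- length(zyg)
  if (n_pairs == 0) stop("empty cohort")
  nv <- prod(config$grid_shape)
  in_cluster <- seq_len(nv) %in% config$signal_cluster

  n_max <- 2L * sum(n_members)
  col_num <- function() numeric(n_max)
  out <- list(family_id = character(n_max), twin_id = integer(n_max),
              zygosity = character(n_max), occasion = integer(n_max),
              age = col_num(), hormone_day1 = col_num(),
              hormone_day2 = col_num(), creatinine_day1 = col_num(),
              creatinine_day2 = col_num(),
              below_limit_day1 = logical(n_max),
              below_limit_day2 = logical(n_max), density = col_num())
  voxmat <- matrix(NA_real_, n_max, nv)
  ri <- 0L
  for (f in seq_len(n_pairs)) {
    rz <- zygosity_rule(zyg[f])
    z1 <- stats::rnorm(p); z2 <- stats::rnorm(p)
    A1 <- Lg %*% z1
    A2 <- Lg %*% (rz * z1 + sqrt(1 - rz^2) * z2)
    Cc <- Lc %*% stats::rnorm(p)
    E1 <- Le %*% stats::rnorm(p)
    E2 <- Le %*% stats::rnorm(p)
    X <- cbind(mu + model$a * A1 + model$c * Cc + model$e * E1,
               mu + model$a * A2 + model$c * Cc + model$e * E2)
    # uncoupled density factors for non-cluster voxels, drawn independently
    # per voxel (columns = occasion) so that voxels outside the cluster do
    # not share a common sampling fluctuation
    Za1 <- matrix(stats::rnorm(nv * 2), nv, 2)
    Za2 <- matrix(stats::rnorm(nv * 2), nv, 2)
    Av <- list(Za1 %*% t(Lg2),
               (rz * Za1 + sqrt(1 - rz^2) * Za2) %*% t(Lg2))
    Cv <- matrix(stats::rnorm(nv * 2), nv, 2) %*% t(Lc2)

    age9 <- stats::rnorm(1, 9.2, 0.11)
    age12 <- age9 + stats::rnorm(1, 2.9, 0.2)
    for (t in seq_len(n_members[f])) {
      drop2 <- stats::runif(1) < config$dropout_rate_occasion2
      # smooth unique-environment fields, correlated across occasions
      S <- gaussian_fields(2, config$grid_shape, config$smoothing_fwhm_voxels)
      f1 <- S[1, ]
      f2 <- re_age * S[1, ] + sqrt(1 - re_age^2) * S[2, ]
      for (o in 1:2) {
        # assay observables drawn for both occasions to keep the RNG stream
        # independent of the dropout draw
        j <- if (o == 1) 1L else 3L     # hormone phenotype index
        jd <- if (o == 1) 2L else 4L    # density phenotype index
        eps <- stats::rnorm(2, 0, config$assay_sd)
        creat <- stats::rlnorm(2, config$creatinine_meanlog,
                               config$creatinine_sdlog)
        if (o == 2 && drop2) next
        raw <- exp(X[j, t] + eps) * creat
        below <- raw < config$detection_limit
        field <- if (o == 1) f1 else f2
        vmap <- mu[jd] + model$a[jd] * Av[[t]][, o] + model$c[jd] * Cv[, o] +
          model$e[jd] * field
        vmap[in_cluster] <- X[jd, t]
        ri <- ri + 1L
        out$family_id[ri] <- sprintf("fam%04d", f)
        out$twin_id[ri] <- t
        out$zygosity[ri] <- zyg[f]
        out$occasion[ri] <- o
        out$age[ri] <- if (o == 1) age9 else age12
        out$hormone_day1[ri] <- if (below[1]) NA_real_ else raw[1]
        out$hormone_day2[ri] <- if (below[2]) NA_real_ else raw[2]
        out$creatinine_day1[ri] <- creat[1]
        out$creatinine_day2[ri] <- creat[2]
        out$below_limit_day1[ri] <- below[1]
        out$below_limit_day2[ri] <- below[2]
        out$density[ri] <- X[jd, t]
        voxmat[ri, ] <- vmap
      }
    }
  }
  keep <- seq_len(ri)
  data <- data.frame(family_id = out$family_id[keep],
                     twin_id = out$twin_id[keep],
                     zygosity = out$zygosity[keep],
                     sex = config$sex,
                     occasion = out$occasion[keep],
                     age = out$age[keep],
                     hormone_day1 = out$hormone_day1[keep],
                     hormone_day2 = out$hormone_day2[keep],
                     creatinine_day1 = out$creatinine_day1[keep],
                     creatinine_day2 = out$creatinine_day2[keep],
                     below_limit_day1 = out$below_limit_day1[keep],
                     below_limit_day2 = out$below_limit_day2[keep],
                     density = out$density[keep],
                     voxel_map_path = NA_character_,
                     stringsAsFactors = FALSE)
  cohort <- list(data = data,
                 voxels = voxmat[keep, , drop = FALSE],
                 grid_shape = config$grid_shape,
                 signal_cluster = config$signal_cluster,
                 detection_limit = config$detection_limit,
                 phenotypes = model$phenotypes,
                 occasions = c("age_9", "age_12"),
                 truth = model)
  class(cohort) <- "twin_cohort"
  cohort
}

#' @export
print.twin_cohort <- function(x, ...) {
  d <- x$data
  fam <- unique(d[, c("family_id", "zygosity")])
  cat(sprintf("twin_cohort: %d individual-occasion rows, %d families (%d MZ, %d DZ)\n",
              nrow(d), nrow(fam), sum(fam$zygosity == "MZ"),
              sum(fam$zygosity == "DZ")))
  cat(sprintf("  voxel grid %s, %d signal voxels\n",
              paste(x$grid_shape, collapse = "x"), length(x$signal_cluster)))
  invisible(x)
}
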