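#' Write a cohort to disk
#'
#' The tabular part goes to \code{cohort.csv} (one row per
#' individual-occasion; missing phenotypes as empty fields) plus a
#' \code{meta.json} sidecar (grid shape, signal cluster, detection limit,
#' labels); one NIfTI-1 volume per individual-occasion goes to
#' \code{maps/}.  \code{\link{read_cohort}} round-trips the result.
#'
#' @param cohort a \code{twin_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.create(dir, showWarnings = FALSE, recursive = TRUE) &&
      !dir.exists(dir))
    stop("cannot create directory ", dir)
  mapdir <- file.path(dir, "maps")
  dir.create(mapdir, showWarnings = FALSE)
  d <- cohort$data
  if (!is.null(cohort$voxels)) {
    paths <- sprintf("maps/%s_t%d_o%d.nii.gz", d$family_id, d$twin_id,
                     d$occasion)
    for (i in seq_len(nrow(d))) {
      RNifti::writeNifti(array(cohort$voxels[i, ], dim = cohort$grid_shape),
                         file.path(dir, paths[i]))
    }
    d$voxel_map_path <- paths
  }
  utils::write.csv(d, file.path(dir, "cohort.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(
    list(grid_shape = cohort$grid_shape,
         signal_cluster = cohort$signal_cluster,
         detection_limit = cohort$detection_limit,
         phenotypes = cohort$phenotypes, occasions = cohort$occasions),
    file.path(dir, "meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir directory containing \code{cohort.csv}, \code{meta.json} and
#'   \code{maps/}.
#' @return a \code{twin_cohort} (without the ground-truth model, which is not
#'   serialized).
#' @export
read_cohort <- function(dir) {
  d <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE,
                       na.strings = "")
  d$below_limit_day1 <- as.logical(d$below_limit_day1)
  d$below_limit_day2 <- as.logical(d$below_limit_day2)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  voxels <- NULL
  if (!is.null(d$voxel_map_path) && !all(is.na(d$voxel_map_path))) {
    voxels <- t(vapply(d$voxel_map_path, function(pp) {
      as.vector(RNifti::readNifti(file.path(dir, pp)))
    }, numeric(prod(meta$grid_shape))))
    rownames(voxels) <- NULL
  }
  cohort <- list(data = d, voxels = voxels,
                 grid_shape = as.integer(meta$grid_shape),
                 signal_cluster = as.integer(meta$signal_cluster),
                 detection_limit = meta$detection_limit,
                 phenotypes = meta$phenotypes, occasions = meta$occasions,
                 truth = NULL)
  class(cohort) <- "twin_cohort"
  cohort
}
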