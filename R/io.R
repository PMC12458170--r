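#' Read and write FSL-dialect gradient tables
#'
#' The bval file is one row of space-separated b-values; the bvec file is
#' three rows (x, y, z components), one column per volume.
#'
#' @param bval_path,bvec_path file paths.
#' @return `read_gradient_table()`: list with `bvals` (numeric vector) and
#'   `bvecs` (n x 3 matrix, one row per volume).
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  })
  rows <- rows[vapply(rows, length, integer(1)) > 0]
  if (length(rows) != 3) stop("bvec file must have exactly 3 rows")
  if (length(unique(vapply(rows, length, integer(1)))) != 1) {
    stop("bvec rows differ in length")
  }
  bvecs <- t(do.call(rbind, rows))
  if (length(bvals) != nrow(bvecs)) {
    stop("bval has ", length(bvals), " entries but bvec has ",
         nrow(bvecs), " columns")
  }
  list(bvals = bvals, bvecs = bvecs)
}

#' @rdname read_gradient_table
#' @param scheme an [acquisition_scheme()] to write.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")
  }), bvec_path)
  invisible(NULL)
}

#' Read a 4D DWI volume with its gradient table
#'
#' Loads a NIfTI-1 volume and FSL bval/bvec files, checks that the volume
#' count matches the gradient table, and renormalizes gradient directions
#' whose norm deviates from 1 by at most 1e-3 (erroring beyond that).
#'
#' @param nifti_path path to the 4D NIfTI file.
#' @param bval_path,bvec_path gradient-table paths.
#' @return list with `dwi` (4D array) and `scheme`
#'   ([acquisition_scheme()]).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI volume")
  gt <- read_gradient_table(bval_path, bvec_path)
  if (dim(arr)[4] != length(gt$bvals)) {
    stop("NIfTI has ", dim(arr)[4], " volumes but the gradient table has ",
         length(gt$bvals))
  }
  dwi <- gt$bvals > 0
  nrm <- sqrt(rowSums(gt$bvecs^2))
  if (any(dwi & nrm < 1e-12)) {
    stop("zero gradient vector on a b > 0 volume")
  }
  off <- abs(nrm - 1)
  if (any(off[dwi] > 1e-3)) {
    stop("gradient directions deviate from unit norm by up to ",
         format(max(off[dwi])), " (tolerance 1e-3)")
  }
  gt$bvecs[dwi, ] <- gt$bvecs[dwi, , drop = FALSE] / nrm[dwi]
  list(dwi = arr, scheme = acquisition_scheme(gt$bvals, gt$bvecs))
}

#' @rdname read_dwi
#' @param dwi 4D array to write.
#' @param scheme the matching [acquisition_scheme()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, scheme, prefix) {
  RNifti::writeNifti(RNifti::asNifti(dwi), paste0(prefix, ".nii.gz"))
  write_gradient_table(scheme, paste0(prefix, ".bval"),
                       paste0(prefix, ".bvec"))
  invisible(paste0(prefix, c(".nii.gz", ".bval", ".bvec")))
}

#' ROI means of a metric map
#'
#' Averages the finite voxels of a metric map within each labelled region.
#' Hemisphere-paired labels listed together in one entry of `label_spec`
#' are merged into a single voxel-count-weighted mean (the subcortical
#' convention); regions listed alone stay separate. A region with no
#' voxels in the label map yields `NA` with a warning.
#'
#' @param metric_map 3D numeric array.
#' @param label_map 3D integer array of the same dimensions.
#' @param label_spec named list mapping ROI name to the integer label(s)
#'   belonging to it.
#' @return data.frame with columns `roi`, `mean`, `n_voxels`.
#' @export
extract_roi_means <- function(metric_map, label_map, label_spec) {
  if (!all(dim(metric_map) == dim(label_map))) {
    stop("metric map and label map dimensions differ")
  }
  out <- data.frame(roi = names(label_spec), mean = NA_real_,
                    n_voxels = 0L)
  for (i in seq_along(label_spec)) {
    sel <- label_map %in% label_spec[[i]]
    vals <- metric_map[sel]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) {
      warning("ROI '", names(label_spec)[i], "' has no finite voxels")
      next
    }
    out$mean[i] <- mean(vals)
    out$n_voxels[i] <- length(vals)
  }
  out
}

#' Write a JSON run manifest
#'
#' Records the resolved configuration, seed and package version of a run
#' so it can be reproduced.
#'
#' @param path output JSON path.
#' @param config named list of resolved options.
#' @param seed integer seed of the run.
#' @export
write_run_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "rsikit",
    version = as.character(utils::packageVersion("rsikit")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
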