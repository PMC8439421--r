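#' Export a synthetic dataset to plain-text files
#'
#' Writes, under `out_dir`: one CSV matrix per run (`localizer.csv`,
#' `adaptation_1.csv`, ...; rows = volumes, columns = voxels), the paradigms
#' as CSV + JSON sidecars, and the per-voxel ground truth (grid coordinates,
#' HRF parameters, neural-model gains) as `ground_truth.json`.
#'
#' @param dataset A [simulate_dataset()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_dataset_csv <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_matrix <- function(get) {
    vals <- lapply(dataset$voxels, get)
    m <- do.call(cbind, lapply(vals, `[[`, "values"))
    colnames(m) <- paste0("voxel_", vapply(dataset$voxels, `[[`, 0,
                                           "voxel_id"))
    m
  }
  utils::write.csv(run_matrix(function(v) v$runs$localizer),
                   file.path(out_dir, "localizer.csv"), row.names = FALSE)
  for (r in 1:3) {
    utils::write.csv(run_matrix(function(v) v$runs$adaptation[[r]]),
                     file.path(out_dir, sprintf("adaptation_%d.csv", r)),
                     row.names = FALSE)
  }
  write_paradigm_csv(dataset$paradigms$localizer,
                     file.path(out_dir, "paradigm_localizer.csv"))
  for (r in 1:3) {
    write_paradigm_csv(dataset$paradigms$adaptation[[r]],
                       file.path(out_dir,
                                 sprintf("paradigm_adaptation_%d.csv", r)))
  }
  truth <- lapply(dataset$voxels, function(v) {
    list(voxel_id = v$voxel_id, coords = as.integer(v$coords),
         active = v$active, hrf = unclass(v$hrf),
         neural = list(base_gain = v$neural$base_gain,
                       duration_gain = as.list(v$neural$duration_gain),
                       decrement_duration_gain =
                         as.list(v$neural$decrement_duration_gain),
                       decrement_ratio = v$neural$decrement_ratio))
  })
  jsonlite::write_json(list(seed = dataset$seed, config = dataset$config,
                            voxels = truth),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a CSV-exported dataset back into time courses
#'
#' @param dir Directory written by [write_dataset_csv()].
#' @param tr_s Repetition time (s).
#' @return List with `runs` (named list of per-voxel [time_course()] lists)
#'   and `paradigms`.
#' @export
read_dataset_csv <- function(dir, tr_s = 1) {
  read_run <- function(name) {
    m <- utils::read.csv(file.path(dir, paste0(name, ".csv")))
    lapply(m, function(col) time_course(col, tr_s = tr_s, unit = "raw",
                                        origin = name))
  }
  runs <- list(localizer = read_run("localizer"),
               adaptation = lapply(1:3, function(r) {
                 read_run(sprintf("adaptation_%d", r))
               }))
  paradigms <- list(
    localizer = read_paradigm_csv(file.path(dir, "paradigm_localizer.csv")),
    adaptation = lapply(1:3, function(r) {
      read_paradigm_csv(file.path(dir,
                                  sprintf("paradigm_adaptation_%d.csv", r)))
    })
  )
  list(runs = runs, paradigms = paradigms)
}

#' Export a run as a 4D NIfTI volume
#'
#' Arranges the voxels on their grid coordinates and writes an
#' `(x, y, z, t)` NIfTI file (requires the RNifti package).
#'
#' @param dataset A [simulate_dataset()] object.
#' @param run `"localizer"` or 1-3 for an adaptation run.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_dataset_nifti <- function(dataset, run, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  get <- if (identical(run, "localizer")) {
    function(v) v$runs$localizer
  } else {
    function(v) v$runs$adaptation[[run]]
  }
  dims <- dataset$config$grid_dims
  n_t <- length(get(dataset$voxels[[1]])$values)
  arr <- array(0, dim = c(dims, n_t))
  for (v in dataset$voxels) {
    arr[v$coords[1], v$coords[2], v$coords[3], ] <- get(v)$values
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(3, 3, 3, get(dataset$voxels[[1]])$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}
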