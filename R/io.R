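# On-disk interchange: 4D NIfTI runs, 3D NIfTI masks, TSV motion and events
# tables, JSON ground truth.

#' Write a simulated condition run set to disk
#'
#' Emits one 4D NIfTI per subject (`sub-<i>_bold.nii.gz`), a parcel label
#' volume (`parcels.nii.gz`), a tissue label volume (`tissue.nii.gz`,
#' 1 = GM, 2 = WM, 3 = CSF), per-subject motion TSVs (6 parameters plus
#' first temporal derivatives), and a ground-truth JSON (condition, TR,
#' coupling, shared signal).
#'
#' @param run_set An `isc_run_set` from [simulate_naturalistic_run()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run_set <- function(run_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- run_set$geometry
  for (nm in names(run_set$subjects)) {
    sub <- run_set$subjects[[nm]]
    arr <- array(sub$bold, dim = c(g$dim, ncol(sub$bold)))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(2, 2, 2, run_set$tr)
    RNifti::writeNifti(img, file.path(dir, paste0(nm, "_bold.nii.gz")))
    mot <- as.data.frame(sub$motion)
    dmot <- as.data.frame(rbind(0, diff(sub$motion)))
    names(dmot) <- paste0(names(mot), "_deriv")
    utils::write.table(cbind(mot, dmot),
                       file.path(dir, paste0(nm, "_motion.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  RNifti::writeNifti(array(g$parcel_id, dim = g$dim),
                     file.path(dir, "parcels.nii.gz"))
  RNifti::writeNifti(array(as.integer(g$tissue), dim = g$dim),
                     file.path(dir, "tissue.nii.gz"))
  jsonlite::write_json(
    list(condition = run_set$condition, type = run_set$type, tr = run_set$tr,
         coupling = as.list(run_set$truth$coupling),
         shared = run_set$truth$shared,
         parcels = g$parcels),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a 4D NIfTI run as a voxel x time matrix
#'
#' @param path NIfTI file path.
#' @return List with `data` (voxel x time matrix, linear voxel index order),
#'   `dim` (spatial dimensions) and `tr` (from the 4th pixdim).
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  list(data = matrix(as.vector(img), nrow = prod(d[1:3]), ncol = d[4]),
       dim = d[1:3], tr = RNifti::pixdim(img)[4])
}

#' Write a localizer events table
#'
#' Standard three-column events TSV (`onset`, `duration`, `condition`).
#'
#' @param design Data frame with `onset`, `duration`, `condition`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_events <- function(design, path) {
  utils::write.table(design[, c("onset", "duration", "condition")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localizer events table
#'
#' @param path Events TSV with columns `onset`, `duration`, `condition`.
#' @return Data frame.
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a long-format ISC table as TSV
#'
#' @param table ISC table (e.g., from [run_isc_pipeline()]).
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_isc_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
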