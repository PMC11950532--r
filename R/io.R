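#' Write a volume as NIfTI-1
#'
#' Volumes are written gzip-compressed with 1 mm isotropic voxels and an
#' identity orientation. Images use a double-precision datatype so values
#' round-trip exactly; atlas label volumes should be written with
#' `datatype = "int32"`.
#'
#' @param volume 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage datatype.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  img <- RNifti::asNifti(volume, internal = FALSE)
  RNifti::pixdim(img) <- c(1, 1, 1)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return a numeric array.
#' @export
read_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path, internal = FALSE))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write a phantom dataset to disk
#'
#' Produces one NIfTI-1 file per subject per channel
#' (`<id>_chan-<c>.nii.gz`), the atlas (`atlas.nii.gz`, integer labels), a
#' BIDS-style `participants.tsv` (`participant_id`, `age`, `sex`, `group`,
#' one path column per channel), and a JSON ground-truth manifest. The files
#' round-trip bit-exactly through [read_volume()] and
#' [read_participants()].
#'
#' @param cohort a [sample_cohort()] data.frame.
#' @param volumes a [render_cohort()] list, one entry per cohort row.
#' @param atlas a [build_atlas()] result.
#' @param manifest a [ground_truth_manifest()] (optional, may be `NULL`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the participants table with path columns.
#' @export
write_dataset <- function(cohort, volumes, atlas, manifest, out_dir) {
  missing_ids <- setdiff(cohort$participant_id, names(volumes))
  if (length(missing_ids)) {
    stop("no rendered volume for subject(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_chan <- length(volumes[[1]]$channels)
  paths <- matrix("", nrow(cohort), n_chan)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$participant_id[i]
    for (c in seq_len(n_chan)) {
      rel <- sprintf("%s_chan-%d.nii.gz", id, c)
      write_volume(volumes[[id]]$channels[[c]], file.path(out_dir, rel))
      paths[i, c] <- rel
    }
  }
  write_volume(atlas$labels, file.path(out_dir, "atlas.nii.gz"), datatype = "int32")
  utils::write.table(
    atlas$region_table, file.path(out_dir, "atlas_regions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  tab <- cohort
  for (c in seq_len(n_chan)) tab[[sprintf("chan%d_path", c)]] <- paths[, c]
  utils::write.table(
    format(tab, digits = 17, trim = TRUE, scientific = FALSE),
    file.path(out_dir, "participants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(manifest)) {
    jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tab)
}

#' Read a participants table written by [write_dataset()]
#'
#' @param path path to `participants.tsv`.
#' @return a data.frame.
#' @export
read_participants <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = NA, stringsAsFactors = FALSE)
}
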