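# Format I/O glue: TIFF stacks, distance-table CSVs, and the convert
# dispatcher. Stacks carry their micrometre calibration in a JSON sidecar
# (one channel per multi-page TIFF file).

#' Write a voxel stack as multi-page TIFF files
#'
#' One 32-bit float TIFF per channel (`<prefix>_nuclear.tif`,
#' `<prefix>_tumor.tif`), plus `<prefix>_meta.json` holding spacing and
#' origin in micrometres.
#'
#' @param stack a `voxel_stack`.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_stack_tiff <- function(stack, prefix) {
  scale <- max(1, max(stack$nuclear), max(stack$tumor))
  files <- c(nuclear = paste0(prefix, "_nuclear.tif"),
             tumor = paste0(prefix, "_tumor.tif"))
  for (ch in names(files)) {
    a <- stack[[ch]] / scale
    pages <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]))
    tiff::writeTIFF(pages, files[[ch]], bits.per.sample = 32L)
  }
  meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(list(spacing_um = stack$spacing,
                            origin_um = stack$origin,
                            intensity_scale = scale,
                            n_slices = dim(stack$nuclear)[3]),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta = meta))
}

#' Read a voxel stack written by [write_stack_tiff()]
#'
#' @param prefix path prefix used when writing.
#' @return a `voxel_stack`.
#' @export
read_stack_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    arr * meta$intensity_scale
  }
  voxel_stack(rd(paste0(prefix, "_nuclear.tif")),
              rd(paste0(prefix, "_tumor.tif")),
              spacing = meta$spacing_um, origin = meta$origin_um)
}

#' Write / read a distance table CSV
#'
#' Column layout follows the exported-spreadsheet convention:
#' `organoid_id`, `group`, `cell_id`, `x`, `y`, `z`, `distance_um` and,
#' when present, `normalized_distance_um`.
#'
#' @param table a distance table `data.frame`.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_distance_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Convert between supported on-disk formats
#'
#' Recognized conversions: distance-table CSV round-trips, MTX count
#' directories, mesh OBJ/PLY, and TIFF stack prefixes. Round trips are
#' lossless for integer counts and positions at the written precision.
#'
#' @param src source path (file, directory or stack prefix).
#' @param dst destination path.
#' @param what one of `"distance_csv"`, `"counts_mtx"`, `"mesh"`,
#'   `"stack_tiff"`.
#' @return `dst`, invisibly.
#' @export
convert_file <- function(src, dst,
                         what = c("distance_csv", "counts_mtx", "mesh",
                                  "stack_tiff")) {
  what <- match.arg(what)
  switch(what,
    distance_csv = write_distance_csv(read_distance_csv(src), dst),
    counts_mtx = write_count_matrix(read_count_matrix(src), dst),
    mesh = write_mesh(read_mesh_obj(src), dst),
    stack_tiff = {
      write_stack_tiff(read_stack_tiff(src), dst)
      dst
    })
  invisible(dst)
}
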