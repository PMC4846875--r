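#' Write a synthetic panel to disk
#'
#' Writes the plate map, the per-cell feature table (feature-table mode)
#' or one multi-channel TIFF per batch (image mode, requires the `tiff`
#' package), and the descriptor catalogue, all as plain CSV/TIFF files.
#'
#' @param panel a [generate_panel()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_panel <- function(panel, dir) {
  if (!inherits(panel, "synthetic_panel")) stop_input("not a synthetic_panel")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("plate_map.csv", "descriptor_catalogue.csv"))
  utils::write.csv(panel$plate_map, files[1], row.names = FALSE)
  utils::write.csv(panel$config$catalogue, files[2], row.names = FALSE)
  if (!is.null(panel$features)) {
    f <- file.path(dir, "features.csv")
    utils::write.csv(panel$features, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(panel$images)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_input("writing image-mode panels requires the 'tiff' package")
    for (b in names(panel$images)) {
      img <- panel$images[[b]]
      f <- file.path(dir, paste0(b, ".tiff"))
      chans <- lapply(img$channels, function(ch) ch / max(max(ch), 1))
      tiff::writeTIFF(chans, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read a per-cell feature table written by [write_panel()]
#'
#' @param path CSV file path.
#' @return data.frame with metadata and descriptor columns.
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("compound", "time_min", "replicate"), colnames(x))
  if (length(miss))
    stop_input("feature table lacks columns: ", paste(miss, collapse = ", "))
  x
}

#' Write a Z matrix with its reliability report
#'
#' @param z_matrix matrix from [assemble_z_matrix()].
#' @param reliability optional [reliability_filter()] report.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_z_matrix <- function(z_matrix, reliability = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, "z_matrix.csv")
  utils::write.csv(as.data.frame(z_matrix), f, row.names = TRUE)
  files <- f
  if (!is.null(reliability)) {
    f2 <- file.path(dir, "reliability_report.csv")
    utils::write.csv(as.data.frame(reliability), f2, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}

#' Write label images of a segmentation as 16-bit TIFF plus an area table
#'
#' @param seg a [derive_regions()] result.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_segmentation <- function(seg, dir) {
  if (!inherits(seg, "segmentation_labels")) stop_input("not segmentation_labels")
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("writing label images requires the 'tiff' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (rg in c("nucleus", "cell", "cytoplasm", "perinuclear", "pm")) {
    f <- file.path(dir, paste0(rg, "_labels.tiff"))
    tiff::writeTIFF(seg[[rg]] / 65535, f, bits.per.sample = 16)
    files <- c(files, f)
  }
  n <- max(seg$cell)
  areas <- data.frame(cell = seq_len(n))
  for (rg in c("nucleus", "cell", "cytoplasm", "perinuclear", "pm"))
    areas[[paste0(rg, "_area")]] <- tabulate(seg[[rg]], nbins = n)
  f <- file.path(dir, "region_areas.csv")
  utils::write.csv(areas, f, row.names = FALSE)
  invisible(c(files, f))
}
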