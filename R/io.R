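# Plain-text interfaces: peak lists, quantification tables, contour CSVs and
# TMH annotation tables.

#' Read a peak list (TSV/CSV with columns mz, intensity)
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @return data frame with columns `mz`, `intensity`.
#' @export
read_peak_list <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("mz", "intensity") %in% names(x)))
  x[, c("mz", "intensity")]
}

#' Write a quantification table as TSV
#' @param quant output of [quantify_species()].
#' @param path file path.
#' @export
write_quant_table <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contour series from CSV (frame_id, x_um, y_um)
#' @param path file path.
#' @param pixel_size,temperature metadata forwarded to [contour_series()].
#' @return a [contour_series()].
#' @export
read_contour_csv <- function(path, pixel_size = 1, temperature = 298.15) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame_id", "x_um", "y_um") %in% names(x)))
  frames <- lapply(split(x, x$frame_id), function(d) cbind(d$x_um, d$y_um))
  contour_series(unname(frames), pixel_size, temperature)
}

#' Write a contour series to CSV
#' @param series a [contour_series()].
#' @param path file path.
#' @export
write_contour_csv <- function(series, path) {
  rows <- lapply(seq_along(series$frames), function(i) {
    f <- series$frames[[i]]
    data.frame(frame_id = i, x_um = f[, 1L], y_um = f[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write TMH annotation tables (TSV, 1-based inclusive coordinates)
#' @param path file path.
#' @return data frame with `protein_id`, `start`, `end`, `length` (computed
#'   when absent) and any further columns.
#' @export
read_tmh_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "start", "end") %in% names(x)))
  if (is.null(x$length)) x$length <- x$end - x$start + 1L
  x
}

#' @rdname read_tmh_table
#' @param x annotation data frame.
#' @export
write_tmh_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
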