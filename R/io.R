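#' Write / read a kymograph as TIFF with a JSON sidecar
#'
#' The intensity matrix is stored as an uncompressed 32-bit float TIFF (one
#' page per channel), with counts scaled by `1/scale` to the [0, 1] range
#' the format expects; the scale and the spatial/temporal calibration are
#' recorded in a JSON sidecar (`<file>.json`) so the pair round-trips to
#' float32 precision.
#'
#' @param kymo A [kymograph()].
#' @param file Output TIFF path.
#' @param scale Count value mapped to 1.0 in the file (default 65535).
#' @return `file`, invisibly.
#' @export
write_kymograph <- function(kymo, file, scale = 65535) {
  stopifnot(inherits(kymo, "kymograph"))
  tiff::writeTIFF(kymo$intensity / scale, file, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  sidecar <- list(pixel_size_nm = kymo$pixel_size,
                  line_time_s = kymo$line_time,
                  channel = kymo$channel,
                  scale = scale)
  jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(file) {
  sidecar <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(file, all = FALSE)
  kymograph(img * sidecar$scale,
            pixel_size = sidecar$pixel_size_nm,
            line_time = sidecar$line_time_s,
            channel = sidecar$channel)
}

#' Write / read a data frame as CSV
#'
#' Plain comma-separated UTF-8 with a header row and '.' decimal separator,
#' the dialect used by every trace, localization and result table in the
#' package.
#'
#' @param df Data frame.
#' @param file Path.
#' @return `file` invisibly / the data frame.
#' @export
write_table_csv <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write / read reads as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param file Path.
#' @return `file` invisibly / a named character vector.
#' @export
write_reads_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_reads_fasta
#' @export
read_reads_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Write a ground-truth or result list as JSON
#'
#' @param x A list (data frames allowed).
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_json_record <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(file)
}

#' @rdname write_json_record
#' @export
read_json_record <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
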