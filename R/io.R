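# File-format helpers: droplet CSV dialect and read sets.

#' Read / write a per-droplet cdPCR table
#'
#' The droplet CSV dialect has columns `droplet_id`, `volume_nl`, `ch1`,
#' `ch2`, `valid` (logical), one row per partitioned reaction.
#'
#' @param path file path.
#' @return `read_droplet_csv()` returns a `droplet_panel` data frame.
#' @export
read_droplet_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("droplet_id", "volume_nl", "ch1", "ch2", "valid")
  if (!all(needed %in% names(panel))) {
    stop("droplet CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  panel$valid <- as.logical(panel$valid)
  class(panel) <- c("droplet_panel", "data.frame")
  panel
}

#' @rdname read_droplet_csv
#' @param panel a droplet panel data frame.
#' @export
write_droplet_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Write simulated reads to FASTA or FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output path; FASTQ output assigns a constant high base quality
#'   (the simulator's error model is already baked into the sequences).
#' @param ids optional read identifiers.
#' @param format `"fasta"` or `"fastq"`.
#' @return the path, invisibly.
#' @export
write_reads <- function(reads, path, ids = NULL,
                        format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  if (format == "fastq") {
    qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
      paste(rep("I", n), collapse = "")
    }, character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Read a FASTA/FASTQ read set as a character vector
#'
#' @param path input path.
#' @param format `"fasta"` or `"fastq"`.
#' @return named character vector of sequences.
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(x), names(x))
}
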