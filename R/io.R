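#' Read and write the package's file formats
#'
#' Thin, strict wrappers: FASTA/FASTQ through Biostrings, tab-separated
#' tables with `#` comment headers through base R, ground truth and run
#' configuration through jsonlite. All coordinates in files are 0-based,
#' half-open.
#'
#' @param x Object to write (amplicon, reads, data.frame, list).
#' @param path File path.
#' @name indelscope_io
NULL

#' @rdname indelscope_io
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "amplicon_target")) {
    x <- Biostrings::DNAStringSet(stats::setNames(x$sequence, x$id))
  }
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname indelscope_io
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' @rdname indelscope_io
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "DNAStringSet"))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname indelscope_io
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
}

#' @rdname indelscope_io
#' @param comments Character vector written as `# ` header lines.
#' @export
write_tsv <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname indelscope_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an indel profile as a TSV (signature, count, freq)
#'
#' @param profile An `indel_profile`.
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "indel_profile"))
  f <- profile_freq(profile)
  df <- data.frame(signature = names(profile$counts),
                   count = as.numeric(profile$counts),
                   freq = if (length(f)) as.numeric(f) else numeric(0))
  write_tsv(df, path, comments = c(
    paste0("sample_id=", profile$sample_id),
    paste0("ref_reads=", profile$ref_reads),
    paste0("total_reads=", profile$total_reads)))
}

#' Read an indel profile written by [write_profile_tsv()]
#'
#' @param path File path.
#' @return An `indel_profile`.
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  df <- read_tsv(path)
  indel_profile(stats::setNames(df$count, df$signature),
                ref_reads = as.numeric(meta[["ref_reads"]]),
                sample_id = meta[["sample_id"]])
}

#' @rdname indelscope_io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @rdname indelscope_io
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
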