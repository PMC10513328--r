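#' Read a FASTA file into a sequence tibble
#'
#' Parses a (possibly gzipped, possibly line-wrapped) FASTA file and returns
#' one row per record. The id is the header token before the first
#' whitespace; sequences are uppercased and validated against the IUPAC
#' nucleotide alphabet.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("FASTA file '%s' contains no records", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate sequence id '%s' in '%s'", ids[duplicated(ids)][1], path
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for record '%s'", ids[!nzchar(seqs)][1]))
  }
  check_iupac(seqs, what = ids)
  tibble(id = ids, sequence = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param line_width Sequence line width (default 60).
#' @return `path`, invisibly. Round-trips with [read_fasta()].
#' @export
write_fasta <- function(records, path, line_width = 60) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("id", "sequence") %in% names(records)))
  check_iupac(records$sequence, what = records$id)
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}
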