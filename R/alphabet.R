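# IUPAC nucleotide alphabet: allele sets, complements, heterozygote codes.

IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_LETTERS <- names(IUPAC_SETS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

HET_CODES <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
HOM_LETTERS <- c("A", "C", "G", "T")
HET_LETTERS <- c("R", "Y", "S", "W", "K", "M")

#' IUPAC ambiguity letter for a heterozygous genotype
#'
#' Returns the single-letter encoding of an unordered pair of distinct
#' nucleotides (e.g. A/G -> "R"), the convention used throughout the package
#' to store diploid heterozygotes in one character.
#'
#' @param a,b Character vectors of single nucleotides in `A,C,G,T`.
#' @return Character vector of ambiguity letters.
#' @export
#' @examples
#' iupac_het("A", "G")
iupac_het <- function(a, b) {
  stopifnot(length(a) == length(b))
  bad <- !(a %in% HOM_LETTERS) | !(b %in% HOM_LETTERS) | a == b
  if (any(bad)) {
    abort(sprintf(
      "iupac_het() needs two distinct bases in A,C,G,T; got '%s'/'%s'",
      a[bad][1], b[bad][1]
    ))
  }
  key <- ifelse(a < b, paste0(a, b), paste0(b, a))
  unname(HET_CODES[key])
}

# Split IUPAC letters into their allele sets (list of character vectors).
iupac_alleles <- function(code) {
  strsplit(unname(IUPAC_SETS[code]), "", fixed = TRUE)
}

# Validate that every character of every string is an IUPAC letter.
# `what` names the offending record in the error.
check_iupac <- function(sequences, what = names(sequences)) {
  if (is.null(what)) what <- as.character(seq_along(sequences))
  for (i in seq_along(sequences)) {
    chars <- unique(strsplit(sequences[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, IUPAC_LETTERS)
    if (length(bad) > 0) {
      abort(sprintf(
        "non-IUPAC character '%s' in record '%s'", bad[1], what[i]
      ))
    }
  }
  invisible(sequences)
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Vectorised reverse complement honouring the full ambiguity alphabet
#' (R<->Y, K<->M, S and W self-complementary, N->N). Used to express probe
#' and genotype calls in chip orientation when a probe places on the minus
#' strand.
#'
#' @param sequence Character vector of uppercase IUPAC nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @export
#' @examples
#' revcomp("AAGN") # "NCTT"
revcomp <- function(sequence) {
  check_iupac(sequence, what = sequence)
  comp <- chartr(
    paste(IUPAC_LETTERS, collapse = ""),
    paste(IUPAC_COMPLEMENT[IUPAC_LETTERS], collapse = ""),
    sequence
  )
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""),
    character(1)
  )
}

# Complement of single characters, no reversal (scalar-fast, vectorised).
complement_base <- function(base) {
  out <- IUPAC_COMPLEMENT[base]
  if (anyNA(out)) {
    abort(sprintf("non-IUPAC base '%s'", base[is.na(out)][1]))
  }
  unname(out)
}
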