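#' Normalize an RNA sequence string
#'
#' Uppercases, converts DNA-style T to U and validates the alphabet. All
#' sequence inputs in the package pass through this function, so downstream
#' code can assume uppercase ACGU.
#'
#' @param x character vector of sequences.
#' @return character vector over the alphabet A, C, G, U.
#' @export
#' @examples
#' normalize_rna("acgt")  # "ACGU"
normalize_rna <- function(x) {
  if (!is.character(x) || any(is.na(x))) stop("sequences must be character, non-NA")
  x <- chartr("tT", "uU", x)
  x <- toupper(x)
  if (any(nchar(x) == 0L)) stop("empty sequence")
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid characters in sequence: ",
         paste(unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), ""))), collapse = ", "))
  }
  x
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick reverse complement (A<->U, C<->G), the relation by which an
#' antisense probe is derived from its target region.
#'
#' @param x character vector of RNA sequences (T accepted, normalized to U).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- normalize_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# split a sequence into an integer code vector A=0 C=1 G=2 U=3 (0-based, for C++)
encode_rna <- function(seq) {
  m <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  unname(m[strsplit(seq, "")[[1]]])
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a named
#' character vector of normalized RNA sequences.
#'
#' @param path path to a FASTA file (RNA or DNA; T is normalized to U).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(normalize_rna(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
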