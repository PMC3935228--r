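# IUPAC nucleotide alphabet and low-level sequence helpers.

# Bitmask encoding: A=1, C=2, G=4, T=8. A gap carries no information and
# never intersects anything, including another gap.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  "-" = 0L
)

IUPAC_LETTERS <- names(IUPAC_MASK)

#' Split a sequence string into a character vector of residues
#' @param x a single sequence string.
#' @return character vector of single residues.
#' @keywords internal
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate residues of one sequence against the IUPAC alphabet
#'
#' @param x uppercase sequence string.
#' @param id record identifier used in error messages.
#' @return invisibly `TRUE`; errors on the first offending column.
#' @keywords internal
validate_residues <- function(x, id = "<sequence>") {
  if (!nzchar(x)) stop("record '", id, "': empty sequence", call. = FALSE)
  ch <- seq_chars(x)
  bad <- which(!(ch %in% IUPAC_LETTERS))
  if (length(bad)) {
    stop("record '", id, "': non-IUPAC character '", ch[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Ambiguity codes are complemented onto their complementary sets
#' (R to Y, K to M, B to V, ...); gaps are preserved.
#'
#' @param x a single IUPAC sequence string.
#' @return the reverse-complemented string.
#' @examples
#' revcomp("AAAAGCATGRGCTGTAACAA")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  validate_residues(x, "<revcomp input>")
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(seq_chars(comp)), collapse = "")
}

#' Integer IUPAC bitmasks for a residue vector
#' @param ch character vector of single uppercase residues.
#' @keywords internal
iupac_mask <- function(ch) {
  m <- IUPAC_MASK[ch]
  if (anyNA(m)) stop("non-IUPAC character '", ch[which(is.na(m))[1]], "'",
                     call. = FALSE)
  unname(m)
}

#' Is each residue an unambiguous A/C/G/T?
#' @keywords internal
is_unambiguous <- function(ch) ch %in% c("A", "C", "G", "T")
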