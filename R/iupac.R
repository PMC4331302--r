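# IUPAC nucleotide algebra: every code is a bitmask over {A=1, C=2, G=4, T=8};
# two codes are compatible iff their masks intersect. This is the matching
# semantics used by in-silico PCR tools (primersearch, ecoPCR): a degenerate
# primer base anneals to any template base in its expansion set.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# mask value -> minimal IUPAC letter covering it
.MASK_LETTER <- {
  x <- character(15L)
  x[.IUPAC_MASK] <- names(.IUPAC_MASK)
  x
}

.GAP_CHARS <- c("-", ".")

# Split a sequence string into single characters.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Encode a gap-free IUPAC string as a mask vector; invalid letters error.
seq_mask <- function(seq, what = "sequence") {
  ch <- seq_chars(seq)
  m <- .IUPAC_MASK[ch]
  if (anyNA(m)) {
    bad <- unique(ch[is.na(m)])
    stop_user(what, " contains non-IUPAC letters: ",
              paste(sQuote(bad), collapse = ", "))
  }
  unname(m)
}

#' Test whether a primer base can pair with a template base
#'
#' IUPAC-aware single-base compatibility: two codes match when their
#' expansion sets intersect (e.g. R = \{A,G\} matches A). A template `N`
#' (typically a sequencing ambiguity rather than true degeneracy) is
#' governed by `template_n`: under `"permissive-match"` it matches any
#' primer base; under `"count-as-mismatch"` it matches none.
#'
#' @param primer_base single IUPAC letter from the primer (5'->3').
#' @param template_base single IUPAC letter from the template.
#' @param template_n how to treat a template `N`; see Details.
#' @return logical scalar.
#' @examples
#' iupac_match("R", "A")                            # TRUE
#' iupac_match("C", "T")                            # FALSE
#' iupac_match("A", "N", "count-as-mismatch")       # FALSE
#' @export
iupac_match <- function(primer_base, template_base,
                        template_n = c("permissive-match", "count-as-mismatch")) {
  template_n <- match.arg(template_n)
  pm <- unname(.IUPAC_MASK[primer_base])
  tm <- unname(.IUPAC_MASK[template_base])
  if (is.na(pm)) stop_user("invalid IUPAC letter in primer: ", sQuote(primer_base))
  if (is.na(tm)) stop_user("invalid IUPAC letter in template: ", sQuote(template_base))
  if (template_base == "N" && template_n == "count-as-mismatch") return(FALSE)
  bitwAnd(pm, tm) > 0L
}

#' Reverse complement of an IUPAC sequence
#'
#' Complements degenerate codes correctly (R<->Y, K<->M, B<->V, D<->H;
#' S, W and N are self-complementary) and reverses the string.
#'
#' @param seq character vector of gap-free IUPAC sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGT")   # "ACGT" (palindrome)
#' revcomp("GGTGGTGCATGGCCGTTCTTAGTT")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  ok <- !grepl("[^ACGTMRWSYKVHDBN]", seq)
  if (!all(ok)) {
    stop_user("revcomp: non-IUPAC letters in sequence(s): ",
              paste(sQuote(seq[!ok]), collapse = ", "))
  }
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", seq)
  vapply(comp, function(s) {
    paste(rev(seq_chars(s)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Minimal IUPAC letter covering a set of plain/degenerate residues.
iupac_cover <- function(bases) {
  m <- Reduce(bitwOr, .IUPAC_MASK[bases], accumulate = FALSE)
  .MASK_LETTER[m]
}
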