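# Primer objects, match parameters, and the packaged primer set.

#' Define a primer
#'
#' @param name primer name.
#' @param seq 5'->3' sequence over IUPAC codes, length >= 10, no gaps.
#' @return object of class `primer` with elements `name` and `seq`.
#' @examples
#' primer("NemF", "GGGGAAGTATGGTTGCAAA")
#' @export
primer <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(seq), length(seq) == 1L)
  seq <- normalize_seq(seq)
  if (nchar(seq) < 10L) stop_user("primer ", name, " shorter than 10 nt")
  seq_mask(seq, paste0("primer ", name))  # validates letters
  structure(list(name = name, seq = seq), class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3' (%d nt)\n", x$name, x$seq, nchar(x$seq)))
  invisible(x)
}

#' Primer-template matching parameters
#'
#' Controls the binding model used by [scan_primer()] and the amplicon
#' predictors. A site is accepted when its total mismatch count is at most
#' `max_mismatches` AND its mismatches within the last `three_prime_window`
#' primer bases (the 3' end, where a mismatch blocks polymerase extension)
#' number at most `max_three_prime_mismatches`.
#'
#' The defaults (2 body mismatches tolerated, none in the last 3 nt) encode
#' the taxon-discrimination mechanism of the NemF primer: selectivity rests
#' on 3'-terminal mismatches to fungal and plant templates, not on overall
#' divergence. No melting-temperature or duplex free-energy model is used;
#' differing annealing stringencies between PCR rounds can only be
#' expressed as different parameter sets per round.
#'
#' @param max_mismatches maximum mismatches over the whole primer.
#' @param three_prime_window window length (nt) counted from the 3' end.
#' @param max_three_prime_mismatches maximum mismatches inside that window.
#' @param template_n `N` handling on the template; see [iupac_match()].
#' @return object of class `match_params`.
#' @export
match_params <- function(max_mismatches = 2L,
                         three_prime_window = 3L,
                         max_three_prime_mismatches = 0L,
                         template_n = c("permissive-match", "count-as-mismatch")) {
  template_n <- match.arg(template_n)
  max_mismatches <- as.integer(max_mismatches)
  three_prime_window <- as.integer(three_prime_window)
  max_three_prime_mismatches <- as.integer(max_three_prime_mismatches)
  stopifnot(max_mismatches >= 0L, three_prime_window >= 0L,
            max_three_prime_mismatches >= 0L)
  if (max_three_prime_mismatches > max_mismatches) {
    stop_user("max_three_prime_mismatches must not exceed max_mismatches")
  }
  structure(list(max_mismatches = max_mismatches,
                 three_prime_window = three_prime_window,
                 max_three_prime_mismatches = max_three_prime_mismatches,
                 template_n = template_n),
            class = "match_params")
}

#' The packaged primer set
#'
#' The three primers of the semi-nested nematode SSU strategy: NemF (the
#' nematode/metazoan-selective forward primer used in the first round),
#' NF1 (internal forward primer of the second round) and 18Sr2b (the
#' reverse primer shared by both rounds). Also shipped as
#' `inst/extdata/primers.tsv`.
#'
#' @return named list of [primer()] objects.
#' @export
default_primers <- function() {
  list(
    NemF   = primer("NemF",   "GGGGAAGTATGGTTGCAAA"),
    NF1    = primer("NF1",    "GGTGGTGCATGGCCGTTCTTAGTT"),
    `18Sr2b` = primer("18Sr2b", "TACAAAGGGCAGGGACGTAAT")
  )
}

#' Read a primer definition file
#'
#' TSV with two columns (name, sequence), no header.
#'
#' @param path primer TSV.
#' @return named list of [primer()] objects.
#' @export
read_primers <- function(path) {
  if (!file.exists(path)) stop_user("primer file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#",
                           col.names = c("name", "seq"),
                           colClasses = "character")
  ps <- Map(primer, tab$name, tab$seq)
  stats::setNames(ps, tab$name)
}

#' Per-position mismatch vector of a primer against site residues
#'
#' Position-wise negation of [iupac_match()] along the primer (5'->3').
#' This is the vector that specificity tables render in dot notation
#' (FALSE = conserved = dot).
#'
#' @param primer a [primer()].
#' @param site_residues string of the same length as the primer, in primer
#'   orientation.
#' @param template_n template `N` policy; see [iupac_match()].
#' @return logical vector, TRUE at mismatching positions.
#' @export
count_mismatch_positions <- function(primer, site_residues,
                                     template_n = c("permissive-match",
                                                    "count-as-mismatch")) {
  template_n <- match.arg(template_n)
  stopifnot(inherits(primer, "primer"))
  if (nchar(site_residues) != nchar(primer$seq)) {
    stop_user("site residues length (", nchar(site_residues),
              ") differs from primer length (", nchar(primer$seq), ")")
  }
  pm <- seq_mask(primer$seq, "primer")
  tch <- seq_chars(site_residues)
  tm <- seq_mask(site_residues, "site residues")
  if (template_n == "count-as-mismatch") tm[tch == "N"] <- 0L
  bitwAnd(pm, tm) == 0L
}
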