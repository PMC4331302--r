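# Sliding-window primer placement with the 3'-window mismatch rule.

empty_sites <- function() {
  out <- data.frame(record_id = character(), strand = character(),
                    start = integer(), end = integer(),
                    n_mismatches = integer(),
                    n_three_prime_mismatches = integer(),
                    stringsAsFactors = FALSE)
  out$mismatch_vector <- list()
  out
}

#' Scan a template for primer binding sites
#'
#' Slides the primer over every offset of an ungapped template and keeps
#' placements passing the mismatch model of [match_params()]. On the plus
#' strand the primer is compared 5'->3' directly; on the minus strand its
#' reverse complement is matched against the plus-strand template (the
#' footprint of a reverse primer), and the mismatch vector is reported in
#' primer 5'->3' orientation so that the 3'-window rule always refers to
#' the primer's own 3' end.
#'
#' Coordinates are 1-based and inclusive on the template plus strand, so
#' `end - start + 1` equals the primer length. Sites are sorted by
#' (n_mismatches, start); a template shorter than the primer yields an
#' empty result, not an error.
#'
#' @param template ungapped template sequence (single string).
#' @param primer a [primer()].
#' @param strand `"plus"` or `"minus"`.
#' @param params a [match_params()].
#' @param record_id id stored in the result rows.
#' @return data.frame of binding sites with columns `record_id`, `strand`,
#'   `start`, `end`, `n_mismatches`, `n_three_prime_mismatches` and a
#'   list-column `mismatch_vector` (logical, primer 5'->3').
#' @export
scan_primer <- function(template, primer, strand = c("plus", "minus"),
                        params = match_params(), record_id = "template") {
  strand <- match.arg(strand)
  stopifnot(inherits(primer, "primer"), inherits(params, "match_params"),
            is.character(template), length(template) == 1L)
  template <- normalize_seq(template)
  if (grepl("-", template, fixed = TRUE)) {
    stop_user("scan_primer requires an ungapped template")
  }
  k <- nchar(primer$seq)
  L <- nchar(template)
  if (L < k) return(empty_sites())

  pat <- if (strand == "minus") revcomp(primer$seq) else primer$seq
  pm <- seq_mask(pat, "primer")
  tch <- seq_chars(template)
  tm <- .IUPAC_MASK[tch]
  if (anyNA(tm)) {
    bad <- unique(tch[is.na(tm)])
    stop_user("template contains non-IUPAC letters: ",
              paste(sQuote(bad), collapse = ", "))
  }
  tm <- unname(tm)
  if (params$template_n == "count-as-mismatch") tm[tch == "N"] <- 0L

  n_off <- L - k + 1L
  idx <- outer(seq_len(k), 0:(n_off - 1L), `+`)
  mm <- matrix(bitwAnd(pm, tm[idx]) == 0L, nrow = k)   # pm recycles per column
  nmm <- colSums(mm)

  w <- min(params$three_prime_window, k)
  n3 <- if (w == 0L) {
    rep(0, n_off)
  } else if (strand == "plus") {
    colSums(mm[(k - w + 1L):k, , drop = FALSE])
  } else {
    colSums(mm[seq_len(w), , drop = FALSE])   # primer 3' end sits template-left
  }

  keep <- which(nmm <= params$max_mismatches &
                  n3 <= params$max_three_prime_mismatches)
  if (length(keep) == 0L) return(empty_sites())
  keep <- keep[order(nmm[keep], keep)]

  vecs <- lapply(keep, function(j) {
    v <- mm[, j]
    if (strand == "minus") rev(v) else v
  })
  out <- data.frame(record_id = record_id, strand = strand,
                    start = keep, end = keep + k - 1L,
                    n_mismatches = as.integer(nmm[keep]),
                    n_three_prime_mismatches = as.integer(n3[keep]),
                    stringsAsFactors = FALSE)
  out$mismatch_vector <- vecs
  out
}

# Best site of a scan: fewest mismatches, leftmost start (scan_primer's
# sort order already guarantees this); NULL when none.
best_site <- function(sites) {
  if (nrow(sites) == 0L) return(NULL)
  sites[1L, , drop = FALSE]
}
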