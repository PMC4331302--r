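# Amplicon prediction for a primer pair and for the semi-nested tagged
# strategy (round 1: NemF + 18Sr2b; round 2: NF1 + the same 18Sr2b on the
# round-1 product). Amplification is binary per template: no cycle-number
# or efficiency model, since stringency differences between rounds are
# expressed through per-round match parameters.

#' Define a primer pair
#'
#' @param forward,reverse [primer()] objects (both given 5'->3'; the
#'   reverse primer is matched as its reverse complement on the template).
#' @param params [match_params()] used for both primers of this pair.
#' @param min_product,max_product product length bounds in nt, including
#'   both primer footprints. `min_product` must be at least the summed
#'   primer lengths.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, params = match_params(),
                        min_product = 100L, max_product = 2000L) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"),
            inherits(params, "match_params"))
  min_product <- as.integer(min_product)
  max_product <- as.integer(max_product)
  floor_len <- nchar(forward$seq) + nchar(reverse$seq)
  if (min_product < floor_len) {
    stop_user("min_product (", min_product, ") below summed primer lengths (",
              floor_len, ")")
  }
  if (min_product > max_product) stop_user("min_product exceeds max_product")
  structure(list(forward = forward, reverse = reverse, params = params,
                 min_product = min_product, max_product = max_product),
            class = "primer_pair")
}

empty_amplicons <- function() {
  data.frame(record_id = character(), start = integer(), end = integer(),
             length = integer(), seq = character(),
             fwd_primer = character(), rev_primer = character(),
             fwd_mismatches = integer(), rev_mismatches = integer(),
             round = character(), stringsAsFactors = FALSE)
}

#' Predict amplicons of a primer pair on one template
#'
#' The forward primer is scanned on the plus strand and the reverse primer
#' as its reverse complement downstream; every (forward, reverse) site
#' pairing whose product length falls within the pair's bounds is emitted.
#' The product spans the forward site's first base through the reverse
#' site's last base, primer footprints included; coordinates are 1-based
#' inclusive on the template. An empty result means no amplification and
#' is not an error.
#'
#' @param template ungapped template sequence (single string).
#' @param pair a [primer_pair()].
#' @param record_id id stored on the amplicons.
#' @return data.frame of amplicons (`record_id`, `start`, `end`, `length`,
#'   `seq`, primer names, per-primer mismatch counts, `round = "single"`).
#' @export
find_amplicons <- function(template, pair, record_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  template <- normalize_seq(template)
  fwd <- scan_primer(template, pair$forward, "plus", pair$params, record_id)
  if (nrow(fwd) == 0L) return(empty_amplicons())
  rev_ <- scan_primer(template, pair$reverse, "minus", pair$params, record_id)
  if (nrow(rev_) == 0L) return(empty_amplicons())

  combos <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev_)))
  len <- rev_$end[combos$r] - fwd$start[combos$f] + 1L
  ok <- len >= pair$min_product & len <= pair$max_product
  combos <- combos[ok, , drop = FALSE]
  if (nrow(combos) == 0L) return(empty_amplicons())
  start <- fwd$start[combos$f]
  end <- rev_$end[combos$r]
  out <- data.frame(
    record_id = record_id, start = start, end = end,
    length = end - start + 1L,
    seq = substring(template, start, end),
    fwd_primer = pair$forward$name, rev_primer = pair$reverse$name,
    fwd_mismatches = fwd$n_mismatches[combos$f],
    rev_mismatches = rev_$n_mismatches[combos$r],
    round = "single", stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Define a semi-nested amplification strategy
#'
#' Bundles the outer (pre-amplification) and inner pairs, enforcing the
#' semi-nested constraint that both rounds share the same reverse primer.
#'
#' @param outer,inner [primer_pair()] objects.
#' @return object of class `nested_strategy`.
#' @export
nested_strategy <- function(outer, inner) {
  stopifnot(inherits(outer, "primer_pair"), inherits(inner, "primer_pair"))
  if (!identical(outer$reverse$seq, inner$reverse$seq)) {
    stop_user("semi-nested strategy requires identical outer and inner ",
              "reverse primers (got ", outer$reverse$name, " vs ",
              inner$reverse$name, ")")
  }
  structure(list(outer = outer, inner = inner), class = "nested_strategy")
}

#' The packaged semi-nested strategy
#'
#' Outer round NemF + 18Sr2b, inner round NF1 + 18Sr2b, with the package's
#' default match parameters per round (strict 3' window in both).
#'
#' @param outer_params,inner_params per-round [match_params()].
#' @param min_product,max_product product bounds applied to both rounds.
#' @return a [nested_strategy()].
#' @export
default_nested_strategy <- function(outer_params = match_params(),
                                    inner_params = match_params(),
                                    min_product = 100L, max_product = 2000L) {
  p <- default_primers()
  nested_strategy(
    outer = primer_pair(p$NemF, p$`18Sr2b`, outer_params,
                        min_product, max_product),
    inner = primer_pair(p$NF1, p$`18Sr2b`, inner_params,
                        min_product, max_product))
}

#' Predict semi-nested amplicons on one template
#'
#' Round 1 amplifies the template with the outer pair; each round-1
#' product then serves as template for the inner pair. Nested products
#' are reported in coordinates of the ORIGINAL template (`round =
#' "nested"`, with `parent_start`/`parent_end` giving the round-1
#' product), and each lies within its parent by construction. Identical
#' nested coordinates arising through different parents are collapsed.
#'
#' @param template ungapped template sequence.
#' @param strategy a [nested_strategy()] (or separate `outer`/`inner`
#'   pairs via [nested_strategy()]).
#' @param record_id id stored on the amplicons.
#' @return data.frame of nested amplicons (see [find_amplicons()]) with
#'   extra columns `parent_start`, `parent_end`.
#' @export
semi_nested <- function(template, strategy, record_id = "template") {
  stopifnot(inherits(strategy, "nested_strategy"))
  template <- normalize_seq(template)
  round1 <- find_amplicons(template, strategy$outer, record_id)
  if (nrow(round1) == 0L) {
    out <- empty_amplicons()
    out$parent_start <- integer()
    out$parent_end <- integer()
    return(out)
  }
  nested <- lapply(seq_len(nrow(round1)), function(i) {
    prod <- find_amplicons(round1$seq[i], strategy$inner, record_id)
    if (nrow(prod) == 0L) return(NULL)
    prod$start <- prod$start + round1$start[i] - 1L
    prod$end <- prod$end + round1$start[i] - 1L
    prod$parent_start <- round1$start[i]
    prod$parent_end <- round1$end[i]
    prod
  })
  nested <- do.call(rbind, nested)
  if (is.null(nested) || nrow(nested) == 0L) {
    out <- empty_amplicons()
    out$parent_start <- integer()
    out$parent_end <- integer()
    return(out)
  }
  nested$round <- "nested"
  nested <- nested[!duplicated(nested[, c("start", "end")]), , drop = FALSE]
  nested <- nested[order(nested$start, nested$end), , drop = FALSE]
  rownames(nested) <- NULL
  nested
}

#' Per-taxon amplifiability summary of a reference set
#'
#' Runs the semi-nested strategy on every record; a record is amplifiable
#' when it yields at least one nested product. Proportions are shares of
#' amplifiable RECORDS per taxon label at `rank` (templates, not products,
#' so multiple products on one template are not double-counted); records
#' with no label at that rank count as "Unclassified". `amplifiable_fraction`
#' gives, per taxon, the fraction of that taxon's records that amplified.
#'
#' @param refset a [ref_set()].
#' @param strategy a [nested_strategy()].
#' @param rank one of [canonical_ranks()].
#' @param weights optional non-negative per-record weights (named by
#'   record id); proportions are then weight shares among amplifiable
#'   records, emulating template abundance.
#' @return object of class `community_profile`: list with `rank`,
#'   `proportions` (named, sums to 1 when anything amplified),
#'   `n_templates`, `n_amplifiable`, `amplifiable_fraction` (named),
#'   `amplifiable` (named logical per record).
#' @export
taxon_amplification_summary <- function(refset, strategy, rank = "phylum",
                                        weights = NULL) {
  stopifnot(inherits(refset, "ref_set"), inherits(strategy, "nested_strategy"))
  rank <- match.arg(rank, canonical_ranks())
  if (length(refset) == 0L) stop_user("empty reference set")
  amp <- vapply(seq_along(refset$id), function(i) {
    nrow(semi_nested(refset$ungapped[i], strategy, refset$id[i])) > 0L
  }, logical(1))
  names(amp) <- refset$id
  labels <- refset$lineage[[rank]]
  labels[is.na(labels)] <- "Unclassified"
  if (is.null(weights)) {
    w <- stats::setNames(rep(1, length(refset)), refset$id)
  } else {
    if (any(weights < 0)) stop_user("negative weights")
    w <- weights[refset$id]
    if (anyNA(w)) stop_user("weights missing for some record ids")
  }
  props <- numeric(0)
  if (any(amp)) {
    agg <- tapply(w[amp], labels[amp], sum)
    props <- agg / sum(agg)
    props <- props[order(-props, names(props))]
  }
  frac <- tapply(amp, labels, mean)
  structure(list(rank = rank,
                 proportions = as.numeric(props) |> stats::setNames(names(props)),
                 n_templates = length(refset),
                 n_amplifiable = sum(amp),
                 amplifiable_fraction = as.numeric(frac) |> stats::setNames(names(frac)),
                 amplifiable = amp),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> rank=%s, %d/%d template(s) amplifiable\n",
              x$rank, x$n_amplifiable, x$n_templates))
  if (length(x$proportions)) {
    for (i in seq_along(x$proportions)) {
      cat(sprintf("  %-16s %6.1f%%\n", names(x$proportions)[i],
                  100 * x$proportions[i]))
    }
  }
  invisible(x)
}
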