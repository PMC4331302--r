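# Per-position primer conservation within taxon groups, and rendering of
# specificity tables: first row the primer, then the in-group's percent
# conservation per position, then one dot-notation consensus row per
# out-group (dot = consensus equals the primer base).

#' Locate a primer's site columns in an aligned reference set
#'
#' Each record's ungapped sequence is scanned for its best binding site
#' (fewest mismatches, leftmost); the site's template positions are lifted
#' to alignment columns, giving one column vector of primer length per
#' record. The modal column vector — the placement supported by the most
#' records — is returned; records with no passing site, or whose best site
#' maps to a different column run, are reported in `$flagged`, never
#' silently dropped.
#'
#' @param refset an aligned [ref_set()].
#' @param primer a [primer()].
#' @param params a [match_params()]; the default tolerance is usually
#'   loosened here (site location, not amplifiability) via e.g.
#'   `match_params(max_mismatches = 4, max_three_prime_mismatches = 4)`.
#' @return object of class `primer_site`: list with `columns` (integer
#'   vector, one alignment column per primer position), `n_support`,
#'   and `flagged` (data.frame of id + reason).
#' @export
locate_primer_site <- function(refset, primer,
                               params = match_params(max_mismatches = 4L,
                                                     three_prime_window = 3L,
                                                     max_three_prime_mismatches = 4L)) {
  stopifnot(inherits(refset, "ref_set"), inherits(primer, "primer"))
  if (!refset$is_aligned) stop_user("locate_primer_site requires an aligned ref_set")
  if (length(refset) == 0L) stop_user("empty reference set")

  runs <- vector("list", length(refset))
  for (i in seq_along(refset$id)) {
    site <- best_site(scan_primer(refset$ungapped[i], primer,
                                  params = params,
                                  record_id = refset$id[i]))
    if (is.null(site)) next
    map <- alignment_map(refset$seq[i])
    cols <- which(!is.na(map))[site$start:site$end]
    runs[[i]] <- cols
  }
  found <- !vapply(runs, is.null, logical(1))
  if (!any(found)) stop_user("primer site not found in any record")

  keys <- vapply(runs[found], paste, character(1), collapse = ",")
  modal_key <- names(sort(table(keys), decreasing = TRUE))[1]
  columns <- as.integer(strsplit(modal_key, ",", fixed = TRUE)[[1]])

  flagged <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  no_site <- refset$id[!found]
  if (length(no_site)) {
    flagged <- rbind(flagged, data.frame(id = no_site, reason = "no passing site",
                                         stringsAsFactors = FALSE))
  }
  disagree <- refset$id[found][keys != modal_key]
  if (length(disagree)) {
    flagged <- rbind(flagged, data.frame(id = disagree,
                                         reason = "site at non-modal columns",
                                         stringsAsFactors = FALSE))
  }
  structure(list(columns = columns, n_support = sum(keys == modal_key),
                 flagged = flagged),
            class = "primer_site")
}

#' @export
print.primer_site <- function(x, ...) {
  cat(sprintf("<primer_site> columns %d..%d (%d positions), %d supporting record(s), %d flagged\n",
              min(x$columns), max(x$columns), length(x$columns),
              x$n_support, nrow(x$flagged)))
  invisible(x)
}

# Residue matrix (records x primer positions) at the site columns.
site_residue_matrix <- function(refset, columns) {
  chs <- strsplit(refset$seq, "", fixed = TRUE)
  do.call(rbind, lapply(chs, `[`, columns))
}

#' Per-position conservation of a taxon group against a primer
#'
#' For each primer position, the percentage of sequences whose residue at
#' the corresponding alignment column is IUPAC-compatible with the primer
#' base, among sequences with a non-gap residue there (an indel carries no
#' evidence about base identity, so gaps are excluded from numerator and
#' denominator alike). Percentages are rounded half-up to integers; a
#' position where every record is gapped reports NA.
#'
#' @param refset an aligned [ref_set()] (typically one taxon group,
#'   from [subset_by_taxon()]).
#' @param primer a [primer()].
#' @param columns alignment columns from [locate_primer_site()], one per
#'   primer position (a `primer_site` object is also accepted).
#' @param taxon_label label stored on the profile.
#' @param template_n template `N` policy; see [iupac_match()].
#' @return object of class `conservation_profile`: list with `primer`,
#'   `taxon_label`, `n_sequences`, `pct` (integer per position, NA where
#'   no informative residue), `matching` and `total` count vectors.
#' @export
conservation_profile <- function(refset, primer, columns,
                                 taxon_label = "in-group",
                                 template_n = c("permissive-match",
                                                "count-as-mismatch")) {
  template_n <- match.arg(template_n)
  stopifnot(inherits(refset, "ref_set"), inherits(primer, "primer"))
  if (inherits(columns, "primer_site")) columns <- columns$columns
  if (length(refset) == 0L) stop_user("empty reference set")
  k <- nchar(primer$seq)
  if (length(columns) != k) {
    stop_user("columns length (", length(columns),
              ") differs from primer length (", k, ")")
  }
  res <- site_residue_matrix(refset, columns)
  pch <- seq_chars(primer$seq)
  pm <- seq_mask(primer$seq, "primer")
  matching <- integer(k); total <- integer(k)
  for (j in seq_len(k)) {
    col <- res[, j]
    col <- col[col != "-"]
    total[j] <- length(col)
    if (total[j] == 0L) { matching[j] <- 0L; next }
    tm <- .IUPAC_MASK[col]
    if (anyNA(tm)) stop_user("invalid residue at site column ", columns[j])
    if (template_n == "count-as-mismatch") tm[col == "N"] <- 0L
    matching[j] <- sum(bitwAnd(pm[j], unname(tm)) > 0L)
  }
  pct <- ifelse(total > 0L, round_half_up(100 * matching / total), NA_real_)
  structure(list(primer = primer, taxon_label = taxon_label,
                 n_sequences = length(refset),
                 pct = as.integer(pct), matching = matching, total = total),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %s vs %s (n=%d)\n",
              x$primer$name, x$taxon_label, x$n_sequences))
  cat(" ", paste(seq_chars(x$primer$seq), collapse = "   "), "\n")
  cat(" ", formatC(x$pct, width = 3), "\n")
  invisible(x)
}

#' Dot-notation consensus of a taxon group at a primer site
#'
#' Per primer position the consensus is the most frequent non-gap residue
#' when its frequency reaches `majority_threshold`; on a frequency tie, or
#' when no residue reaches the threshold, it falls back to the minimal
#' IUPAC code covering all residues at frequency >= 0.25 (so a 50/50 A/G
#' split renders as R). Positions where the consensus is IUPAC-compatible
#' with the primer base are rendered as '.'; positions with no informative
#' residue as '-'.
#'
#' @inheritParams conservation_profile
#' @param majority_threshold plain-majority cutoff (fraction of non-gap
#'   residues), default 0.5.
#' @return object of class `consensus_row`: list with `taxon_label`,
#'   `consensus` (bases), `display` (dot notation), `majority_threshold`.
#' @export
consensus_row <- function(refset, primer, columns,
                          taxon_label = "out-group",
                          majority_threshold = 0.5) {
  stopifnot(inherits(refset, "ref_set"), inherits(primer, "primer"))
  if (inherits(columns, "primer_site")) columns <- columns$columns
  if (length(refset) == 0L) stop_user("empty reference set")
  k <- nchar(primer$seq)
  if (length(columns) != k) stop_user("columns length differs from primer length")
  res <- site_residue_matrix(refset, columns)
  pch <- seq_chars(primer$seq)
  cons <- character(k)
  for (j in seq_len(k)) {
    col <- res[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) { cons[j] <- "-"; next }
    freq <- table(col) / length(col)
    top <- freq[freq == max(freq)]
    if (length(top) == 1L && top[[1]] >= majority_threshold) {
      cons[j] <- names(top)
    } else {
      common <- names(freq)[freq >= 0.25]
      if (length(common) == 0L) common <- names(top)
      cons[j] <- iupac_cover(common)
    }
  }
  disp <- cons
  informative <- cons != "-"
  hit <- logical(k)
  hit[informative] <- !count_mismatch_positions(
    primer, paste(ifelse(informative, cons, "N"), collapse = ""))[informative]
  disp[informative & hit] <- "."
  structure(list(taxon_label = taxon_label, consensus = cons, display = disp,
                 majority_threshold = majority_threshold),
            class = "consensus_row")
}

#' @export
print.consensus_row <- function(x, ...) {
  cat(sprintf("<consensus_row> %s  %s\n", x$taxon_label,
              paste(x$display, collapse = "")))
  invisible(x)
}

#' Render a primer specificity table
#'
#' Assembles the classic specificity layout: primer bases, the in-group's
#' percent conservation at each position, and one dot-notation consensus
#' row per out-group. Both a fixed-width text rendering and a TSV twin
#' (identical cell values) are produced; positions are numbered 1-based.
#'
#' @param primer a [primer()].
#' @param profiles list of [conservation_profile()] objects (in-group rows).
#' @param consensus_rows list of [consensus_row()] objects (out-group rows).
#' @return object of class `specificity_table`: list with `text` (character
#'   vector of lines) and `table` (data.frame, row label + one column per
#'   primer position).
#' @export
format_specificity_table <- function(primer, profiles, consensus_rows = list()) {
  stopifnot(inherits(primer, "primer"))
  if (inherits(profiles, "conservation_profile")) profiles <- list(profiles)
  if (inherits(consensus_rows, "consensus_row")) consensus_rows <- list(consensus_rows)
  k <- nchar(primer$seq)
  cells <- list(c(primer$name, seq_chars(primer$seq)))
  for (p in profiles) {
    if (length(p$pct) != k) stop_user("profile row length differs from primer")
    cells[[length(cells) + 1L]] <-
      c(p$taxon_label, ifelse(is.na(p$pct), "-", as.character(p$pct)))
  }
  for (cr in consensus_rows) {
    if (length(cr$display) != k) stop_user("consensus row length differs from primer")
    cells[[length(cells) + 1L]] <- c(cr$taxon_label, cr$display)
  }
  mat <- do.call(rbind, cells)
  tab <- as.data.frame(mat[, -1, drop = FALSE], stringsAsFactors = FALSE)
  colnames(tab) <- paste0("pos", seq_len(k))
  tab <- cbind(data.frame(row = mat[, 1], stringsAsFactors = FALSE), tab)
  widths <- apply(mat, 2L, function(col) max(nchar(col)))
  text <- apply(mat, 1L, function(r) {
    paste(mapply(formatC, r, width = widths, MoreArgs = list(flag = "-")),
          collapse = " ")
  })
  structure(list(text = trimws(text, "right"), table = tab, primer = primer),
            class = "specificity_table")
}

#' @export
print.specificity_table <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a specificity table to text and TSV files
#'
#' @param x a `specificity_table` from [format_specificity_table()].
#' @param prefix output path prefix; writes `<prefix>.txt` and `<prefix>.tsv`.
#' @return character vector of the two paths, invisibly.
#' @export
write_specificity_table <- function(x, prefix) {
  stopifnot(inherits(x, "specificity_table"))
  txt <- paste0(prefix, ".txt")
  tsv <- paste0(prefix, ".tsv")
  write_lines_atomic(x$text, txt)
  lines <- c(paste(colnames(x$table), collapse = "\t"),
             apply(x$table, 1L, paste, collapse = "\t"))
  write_lines_atomic(lines, tsv)
  invisible(c(txt, tsv))
}
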