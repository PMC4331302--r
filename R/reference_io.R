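# Reference sequence collections with taxonomy.
#
# A `ref_set` holds marker sequences (optionally as a gapped alignment) plus
# a lineage table over the canonical ranks. Sequences are normalized on
# input: uppercase, RNA U -> T, '.' gaps -> '-'.

#' Canonical taxonomic ranks
#'
#' The fixed rank ladder used for lineage parsing and taxon subsetting:
#' kingdom, phylum, class, order, family, genus, species. Lineage fields
#' beyond species are dropped with a warning.
#'
#' @return character vector of the seven rank names.
#' @export
canonical_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct a reference set
#'
#' Low-level constructor; most users will call [read_fasta()] or
#' [read_aligned_fasta()]. Sequences must already be normalized
#' (uppercase DNA, gaps as '-').
#'
#' @param id character vector of unique record ids.
#' @param seq character vector of (possibly gapped) sequences.
#' @param lineage data.frame with one row per record and the columns of
#'   [canonical_ranks()] (NA where unlabelled), or NULL for all-Unclassified.
#' @param is_aligned logical; if TRUE all sequences must have equal length.
#' @return an object of class `ref_set`.
#' @export
ref_set <- function(id, seq, lineage = NULL, is_aligned = FALSE) {
  stopifnot(is.character(id), is.character(seq), length(id) == length(seq))
  if (length(id) == 0L) stop_user("no records")
  if (any(!nzchar(id))) stop_user("empty record id")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop_user("duplicate record ids: ", paste(dup, collapse = ", "))
  }
  if (is.null(lineage)) {
    lineage <- as.data.frame(
      matrix(NA_character_, length(id), 7L,
             dimnames = list(NULL, canonical_ranks())),
      stringsAsFactors = FALSE)
    lineage$kingdom <- "Unclassified"
  }
  stopifnot(identical(colnames(lineage), canonical_ranks()),
            nrow(lineage) == length(id))
  if (is_aligned) {
    len <- nchar(seq)
    if (length(unique(len)) > 1L) {
      modal <- as.integer(names(sort(table(len), decreasing = TRUE))[1])
      off <- which(len != modal)
      stop_user("aligned sequences have unequal lengths: ",
                paste(sprintf("%s (%d)", id[off], len[off]), collapse = ", "),
                "; expected ", modal)
    }
  }
  structure(
    list(id = unname(id), seq = unname(seq),
         ungapped = unname(gsub("-", "", seq, fixed = TRUE)),
         lineage = lineage, is_aligned = isTRUE(is_aligned)),
    class = "ref_set")
}

#' @export
length.ref_set <- function(x) length(x$id)

#' @export
print.ref_set <- function(x, ...) {
  cat(sprintf("<ref_set> %d record(s)%s\n", length(x),
              if (x$is_aligned)
                sprintf(", aligned (%d columns)", nchar(x$seq[1])) else ""))
  phy <- table(ifelse(is.na(x$lineage$phylum), "NA", x$lineage$phylum))
  cat("  phyla:", paste(sprintf("%s=%d", names(phy), phy), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.ref_set` <- function(x, i) {
  ref_set(x$id[i], x$seq[i], x$lineage[i, , drop = FALSE], x$is_aligned)
}

normalize_seq <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("U.", "T-", seq)
  seq
}

validate_seq_letters <- function(seq, id, allow_gap) {
  pat <- if (allow_gap) "[^ACGTMRWSYKVHDBN-]" else "[^ACGTMRWSYKVHDBN]"
  bad <- grepl(pat, seq)
  if (any(bad)) {
    ch <- unique(unlist(regmatches(seq[bad], gregexpr(pat, seq[bad]))))
    stop_user("invalid sequence letters (", paste(sQuote(ch), collapse = ", "),
              ") in record(s): ", paste(utils::head(id[bad], 5), collapse = ", "))
  }
}

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop_user("input file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop_user("no records in ", path)
  if (!startsWith(first, ">")) {
    stop_user("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_user("malformed FASTA in ", path,
                                                ": ", conditionMessage(e)))
  if (length(set) == 0L) stop_user("no records in ", path)
  list(headers = names(set), seqs = normalize_seq(as.character(set)))
}

#' Read an (unaligned) FASTA reference file
#'
#' One record per FASTA entry. Lowercase and RNA (U) are normalized to
#' uppercase DNA; lineages are taken from the sidecar taxonomy (if given),
#' falling back to a semicolon-delimited lineage in the header description.
#' Records with neither source get kingdom "Unclassified" with a warning.
#'
#' @param path FASTA file.
#' @param taxonomy optional named character vector (id -> semicolon-delimited
#'   lineage), e.g. from [read_taxonomy()].
#' @return a [ref_set()] with `is_aligned = FALSE`.
#' @export
read_fasta <- function(path, taxonomy = NULL) {
  raw <- read_fasta_raw(path)
  ids <- sub("\\s.*$", "", raw$headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop_user("duplicate record ids in ", path, ": ",
                             paste(dup, collapse = ", "))
  validate_seq_letters(raw$seqs, ids, allow_gap = FALSE)
  lin <- lineage_frame(raw$headers, ids, taxonomy)
  ref_set(ids, raw$seqs, lin, is_aligned = FALSE)
}

#' Read a gapped (aligned) FASTA reference file
#'
#' Like [read_fasta()] but sequences may carry gap characters ('-' or '.',
#' normalized to '-') and must all have the same aligned length.
#'
#' @inheritParams read_fasta
#' @return a [ref_set()] with `is_aligned = TRUE`.
#' @export
read_aligned_fasta <- function(path, taxonomy = NULL) {
  raw <- read_fasta_raw(path)
  ids <- sub("\\s.*$", "", raw$headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop_user("duplicate record ids in ", path, ": ",
                             paste(dup, collapse = ", "))
  validate_seq_letters(raw$seqs, ids, allow_gap = TRUE)
  lin <- lineage_frame(raw$headers, ids, taxonomy)
  ref_set(ids, raw$seqs, lin, is_aligned = TRUE)
}

#' Write a reference set to FASTA
#'
#' Headers carry the record id followed by the semicolon-delimited lineage,
#' so that a read/write/read round trip preserves ids, lineages and
#' sequences. Aligned sets are written with their gaps.
#'
#' @param refset a [ref_set()].
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_fasta <- function(refset, path) {
  stopifnot(inherits(refset, "ref_set"))
  lin <- lineage_strings(refset$lineage)
  hdr <- ifelse(nzchar(lin), paste(refset$id, lin), refset$id)
  write_lines_atomic(as.vector(rbind(paste0(">", hdr), refset$seq)), path)
}

lineage_strings <- function(lineage) {
  apply(lineage, 1L, function(r) {
    r <- r[!is.na(r)]
    paste(r, collapse = ";")
  })
}

#' Read a taxonomy sidecar file
#'
#' Two-column TSV, no header: record id, TAB, semicolon-delimited lineage
#' (kingdom down to species).
#'
#' @param path TSV file.
#' @return named character vector mapping id to lineage string.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_user("taxonomy file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           col.names = c("id", "lineage"),
                           colClasses = "character")
  stats::setNames(tab$lineage, tab$id)
}

#' Parse a semicolon-delimited lineage
#'
#' Labels are assigned to the canonical ranks in order, starting at
#' kingdom; fields beyond species are dropped with a warning. A sidecar
#' lineage, when supplied, takes precedence over the header.
#'
#' @param header full FASTA header (id, whitespace, optional lineage).
#' @param sidecar optional named character vector id -> lineage string.
#' @return named character vector over [canonical_ranks()] (NA = unlabelled).
#' @examples
#' parse_lineage("seq1 Eukaryota;Metazoa;Nematoda;Tylenchida")
#' @export
parse_lineage <- function(header, sidecar = NULL) {
  id <- sub("\\s.*$", "", header)
  desc <- sub("^\\S+\\s*", "", header)
  src <- NULL
  if (!is.null(sidecar) && id %in% names(sidecar)) {
    src <- sidecar[[id]]
  } else if (nzchar(desc) && grepl(";|^[A-Za-z]", desc)) {
    src <- desc
  }
  ranks <- canonical_ranks()
  out <- stats::setNames(rep(NA_character_, 7L), ranks)
  if (is.null(src) || !nzchar(trimws(src))) {
    warning("record ", sQuote(id), " has no lineage; using Unclassified",
            call. = FALSE)
    out["kingdom"] <- "Unclassified"
    return(out)
  }
  labels <- trimws(strsplit(src, ";", fixed = TRUE)[[1]])
  labels <- labels[nzchar(labels)]
  if (length(labels) > 7L) {
    warning("lineage for ", sQuote(id), " has ", length(labels),
            " fields; dropping those beyond species", call. = FALSE)
    labels <- labels[1:7]
  }
  if (length(labels) == 0L) {
    out["kingdom"] <- "Unclassified"
    return(out)
  }
  out[ranks[seq_along(labels)]] <- labels
  out
}

lineage_frame <- function(headers, ids, taxonomy) {
  rows <- lapply(headers, parse_lineage, sidecar = taxonomy)
  lin <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(lin) <- canonical_ranks()
  rownames(lin) <- NULL
  lin
}

#' Map an alignment column to an ungapped position
#'
#' For a gapped sequence, returns the 1-based position in the ungapped
#' sequence of the residue at the given 1-based alignment column, or NA
#' when that column is a gap in this sequence.
#'
#' @param aligned_seq a single gapped sequence string.
#' @param column integer vector of 1-based alignment columns.
#' @return integer vector (NA at gap columns).
#' @examples
#' column_to_ungapped("A-CG", 3)  # 2
#' column_to_ungapped("A-CG", 2)  # NA
#' @export
column_to_ungapped <- function(aligned_seq, column) {
  stopifnot(length(aligned_seq) == 1L)
  n <- nchar(aligned_seq)
  if (any(column < 1L | column > n)) {
    stop_user("alignment column out of range 1..", n)
  }
  map <- alignment_map(aligned_seq)
  map[column]
}

# Per-column ungapped index (NA at gaps) for one gapped sequence.
alignment_map <- function(aligned_seq) {
  ch <- seq_chars(aligned_seq)
  gap <- ch == "-"
  map <- cumsum(!gap)
  map[gap] <- NA_integer_
  as.integer(map)
}

#' Subset a reference set by taxon
#'
#' Keeps records whose lineage carries `label` at `rank`; an empty result
#' is allowed and returned as NULL. With `label = "Unclassified"` records
#' with an NA label at that rank are also selected, so that subsets over
#' all labels plus Unclassified partition the set.
#'
#' @param refset a [ref_set()].
#' @param rank one of [canonical_ranks()].
#' @param label taxon label at that rank.
#' @return a [ref_set()] or NULL when no record matches.
#' @export
subset_by_taxon <- function(refset, rank, label) {
  stopifnot(inherits(refset, "ref_set"))
  rank <- match.arg(rank, canonical_ranks())
  lab <- refset$lineage[[rank]]
  keep <- !is.na(lab) & lab == label
  if (label == "Unclassified") keep <- keep | is.na(lab)
  if (!any(keep)) return(NULL)
  refset[keep]
}
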