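# Independent brute-force oracles and fixture builders.
#
# The oracles deliberately avoid the package's matching machinery: base
# compatibility comes from set intersection over Biostrings::IUPAC_CODE_MAP
# and reverse complements from Biostrings::reverseComplement, so agreement
# with scan_primer()/find_amplicons() is a genuine cross-check.

.iupac_sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

oracle_match <- function(p, t, policy = "permissive-match") {
  if (t == "N") return(policy == "permissive-match")
  length(intersect(.iupac_sets[[p]], .iupac_sets[[t]])) > 0
}

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Test every offset, compare every base; returns start/end/n/n3 rows sorted
# like scan_primer (n_mismatches, then start).
oracle_scan <- function(template, pseq, strand = "plus",
                        max_mm = 2, w = 3, max3 = 0,
                        policy = "permissive-match") {
  pat <- if (strand == "minus") oracle_revcomp(pseq) else pseq
  k <- nchar(pat); L <- nchar(template)
  pch <- strsplit(pat, "")[[1]]
  rows <- list()
  if (L >= k) {
    for (i in seq_len(L - k + 1)) {
      tch <- strsplit(substring(template, i, i + k - 1), "")[[1]]
      v <- !mapply(oracle_match, pch, tch, MoreArgs = list(policy = policy))
      if (strand == "minus") v <- rev(v)   # report in primer orientation
      ww <- min(w, k)
      n3 <- if (ww > 0) sum(v[(k - ww + 1):k]) else 0L
      if (sum(v) <= max_mm && n3 <= max3) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i, end = i + k - 1L, n_mismatches = sum(v),
          n_three_prime_mismatches = n3)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      n_mismatches = integer(),
                      n_three_prime_mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$n_mismatches, out$start), , drop = FALSE]
}

# Exhaustive (i, j) pairing oracle for amplicon prediction.
oracle_amplicons <- function(template, fseq, rseq, max_mm = 2, w = 3,
                             max3 = 0, min_len = 100, max_len = 2000) {
  f <- oracle_scan(template, fseq, "plus", max_mm, w, max3)
  r <- oracle_scan(template, rseq, "minus", max_mm, w, max3)
  rows <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    len <- r$end[j] - f$start[i] + 1
    if (len >= min_len && len <= max_len) {
      rows[[length(rows) + 1]] <- data.frame(start = f$start[i],
                                             end = r$end[j], length = len)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_template <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random primer: mostly plain bases, a sprinkle of degenerate codes.
random_primer_seq <- function(k, degenerate_frac = 0.15) {
  plain <- c("A", "C", "G", "T")
  degen <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  ch <- sample(plain, k, replace = TRUE)
  nd <- rbinom(1, k, degenerate_frac)
  if (nd > 0) ch[sample(k, nd)] <- sample(degen, nd, replace = TRUE)
  paste(ch, collapse = "")
}

# Mutate a template so a primer site is planted at `at` (1-based), with
# optional substitutions given as primer-position -> base.
plant_site <- function(template, seq_at_site, at) {
  paste0(substring(template, 1, at - 1), seq_at_site,
         substring(template, at + nchar(seq_at_site)))
}

write_tmp_fasta <- function(headers, seqs, dir = tempdir()) {
  path <- tempfile("refs", tmpdir = dir, fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# The standard four-taxon mock community used across tests: three clean
# taxa and one carrying the 3'-terminal NemF signature (blocked).
fixture_community <- function(seed = 11, n_nem = 30, n_fun = 10,
                              n_tar = 8, n_rot = 6, bg = 0.01) {
  fungal <- taxon_signature("NemF", c("5" = "G", "14" = "C", "19" = "G"))
  cfg <- sim_config(list(
    sim_taxon("Nematoda", n_nem, weight = 3),
    sim_taxon("Fungi", n_fun, fungal, weight = 2,
              lineage = "Fungi;Fungi"),
    sim_taxon("Tardigrada", n_tar, weight = 1),
    sim_taxon("Rotifera", n_rot, weight = 1)
  ), background_sub_rate = bg, seed = seed)
  generate_reference_set(cfg)
}
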