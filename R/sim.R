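# Synthetic reference sets and error-bearing reads with known truth.
#
# Every record is built from one seeded SSU-like base template laid out as
#   5' flank | NemF site | spacer | NF1 site | insert | revcomp(18Sr2b) | 3' flank
# so the outer (NemF/18Sr2b) and inner (NF1/18Sr2b) products exist by
# construction. Taxon signatures substitute specific primer-site positions
# (e.g. the fungal/plant NemF pattern 5->G, 14->C, 19->G whose position-19
# change sits on the primer's 3'-terminal base); background substitutions
# model neutral divergence and never touch primer sites, keeping the
# selectivity mechanism separable from noise.

#' Define a taxon-specific primer-site signature
#'
#' @param primer_name which primer site the substitutions apply to
#'   ("NemF", "NF1" or "18Sr2b" under the default primer set).
#' @param substitutions named character vector: names are 1-based primer
#'   positions (5'->3' of the primer), values replacement bases, each
#'   required to differ from the primer base.
#' @return object of class `taxon_signature`.
#' @examples
#' taxon_signature("NemF", c("5" = "G", "14" = "C", "19" = "G"))
#' @export
taxon_signature <- function(primer_name, substitutions) {
  stopifnot(is.character(primer_name), length(primer_name) == 1L)
  pos <- as.integer(names(substitutions))
  if (anyNA(pos) || any(pos < 1L)) {
    stop_user("signature positions must be positive integers (1-based)")
  }
  subs <- toupper(unname(unlist(substitutions)))
  if (!all(subs %in% c("A", "C", "G", "T"))) {
    stop_user("signature replacements must be A/C/G/T")
  }
  structure(list(primer_name = primer_name,
                 substitutions = stats::setNames(subs, pos)),
            class = "taxon_signature")
}

#' Define one simulated taxon
#'
#' @param label taxon label, placed at phylum rank of the default lineage.
#' @param n number of records.
#' @param signatures list of [taxon_signature()] objects (possibly empty);
#'   applied to every record of this taxon.
#' @param weight relative template abundance of each record of this taxon.
#' @param lineage semicolon-delimited lineage; default
#'   `"Eukaryota;<label>"` so that `label` is the phylum.
#' @return object of class `sim_taxon`.
#' @export
sim_taxon <- function(label, n, signatures = list(), weight = 1,
                      lineage = paste0("Eukaryota;", label)) {
  stopifnot(is.character(label), nzchar(label), n >= 1L, weight >= 0)
  if (inherits(signatures, "taxon_signature")) signatures <- list(signatures)
  stopifnot(all(vapply(signatures, inherits, logical(1), "taxon_signature")))
  structure(list(label = label, n = as.integer(n), signatures = signatures,
                 weight = weight, lineage = lineage),
            class = "sim_taxon")
}

#' Configure the reference-set simulator
#'
#' Defaults follow the geometry of the published assay: 100-nt flanks, a
#' 30-nt spacer between the NemF and NF1 sites, and a 305-nt insert so the
#' NF1->18Sr2b product is 350 nt and its tagged read-out about 410-420 bp.
#'
#' @param taxa list of [sim_taxon()] objects.
#' @param background_sub_rate per-site substitution probability outside
#'   all primer sites, in `[0, 1]`.
#' @param insert_length nt between the NF1 site and the 18Sr2b site.
#' @param flank_length flank length on each side of the amplified region.
#' @param spacer_length nt between the NemF and NF1 sites.
#' @param seed integer; the whole community is reproducible from it.
#' @param primers named list of [primer()] objects providing the sites;
#'   must contain a forward outer, forward inner and reverse primer under
#'   the names used by signatures.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(taxa, background_sub_rate = 0.02,
                       insert_length = 305L, flank_length = 100L,
                       spacer_length = 30L, seed = 1L,
                       primers = default_primers()) {
  if (inherits(taxa, "sim_taxon")) taxa <- list(taxa)
  stopifnot(length(taxa) >= 1L,
            all(vapply(taxa, inherits, logical(1), "sim_taxon")),
            background_sub_rate >= 0, background_sub_rate <= 1,
            insert_length >= 0L, flank_length >= 0L, spacer_length >= 0L)
  for (tx in taxa) {
    for (sg in tx$signatures) {
      pr <- primers[[sg$primer_name]]
      if (is.null(pr)) {
        stop_user("signature references unknown primer: ", sg$primer_name)
      }
      pos <- as.integer(names(sg$substitutions))
      if (any(pos > nchar(pr$seq))) {
        stop_user("signature position beyond ", sg$primer_name, " length")
      }
      pch <- seq_chars(pr$seq)[pos]
      same <- sg$substitutions == pch
      if (any(same)) {
        stop_user("signature replacement equals the ", sg$primer_name,
                  " base at position ",
                  paste(pos[same], collapse = ", "))
      }
    }
  }
  structure(list(taxa = taxa, background_sub_rate = background_sub_rate,
                 insert_length = as.integer(insert_length),
                 flank_length = as.integer(flank_length),
                 spacer_length = as.integer(spacer_length),
                 seed = as.integer(seed), primers = primers),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Template layout bookkeeping: site start positions (1-based) per primer.
template_layout <- function(config) {
  p <- config$primers
  fl <- config$flank_length; sp <- config$spacer_length
  ins <- config$insert_length
  nemf_len <- nchar(p[[1]]$seq); nf1_len <- nchar(p[[2]]$seq)
  rev_len <- nchar(p[[3]]$seq)
  nemf_start <- fl + 1L
  nf1_start <- nemf_start + nemf_len + sp
  rev_start <- nf1_start + nf1_len + ins
  total <- rev_start + rev_len - 1L + fl
  list(starts = stats::setNames(c(nemf_start, nf1_start, rev_start),
                                names(p)[1:3]),
       lengths = stats::setNames(c(nemf_len, nf1_len, rev_len),
                                 names(p)[1:3]),
       total = total)
}

#' Generate a synthetic reference community
#'
#' Builds the base template under the config seed, then derives each
#' record by applying its taxon's signatures exactly (substitutions at
#' the stated primer positions, on the primer's strand) and independent
#' background substitutions outside all primer sites. Identical seeds
#' give byte-identical communities. Because all records share one
#' gap-free coordinate system, the returned reference set is flagged as
#' aligned, so conservation profiling works on it directly.
#'
#' @param config a [sim_config()].
#' @return object of class `mock_community`: list with `refset` (a
#'   [ref_set()]), `truth` (named character, record id -> taxon label),
#'   `abundances` (named numeric weights) and `layout` (site positions).
#' @export
generate_reference_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- template_layout(config)
  p <- config$primers
  with_seed(config$seed, {
    fl1 <- random_dna(config$flank_length)
    sp <- random_dna(config$spacer_length)
    ins <- random_dna(config$insert_length)
    fl2 <- random_dna(config$flank_length)
    base <- paste0(fl1, p[[1]]$seq, sp, p[[2]]$seq, ins,
                   revcomp(p[[3]]$seq), fl2)
    base_ch <- seq_chars(base)

    in_site <- rep(FALSE, lay$total)
    for (nm in names(lay$starts)) {
      in_site[lay$starts[[nm]]:(lay$starts[[nm]] + lay$lengths[[nm]] - 1L)] <- TRUE
    }
    free_pos <- which(!in_site)

    ids <- character(0); seqs <- character(0)
    truth <- character(0); abund <- numeric(0); lineages <- character(0)
    counter <- list()
    for (tx in config$taxa) {
      tmpl <- base_ch
      for (sg in tx$signatures) {
        pr <- p[[sg$primer_name]]
        pos <- as.integer(names(sg$substitutions))
        site_start <- lay$starts[[sg$primer_name]]
        site_len <- lay$lengths[[sg$primer_name]]
        if (sg$primer_name == names(p)[3]) {
          # reverse primer: its site is the revcomp on the plus strand, so
          # primer position i maps to plus-strand offset (len - i + 1) with
          # the complementary base substituted.
          tpos <- site_start + (site_len - pos)
          repl <- vapply(sg$substitutions, function(b) {
            chartr("ACGT", "TGCA", b)
          }, character(1))
        } else {
          tpos <- site_start + pos - 1L
          repl <- sg$substitutions
        }
        tmpl[tpos] <- repl
      }
      start_i <- (counter[[tx$label]] %||% 0L)
      counter[[tx$label]] <- start_i + tx$n
      for (i in seq_len(tx$n)) {
        rec <- tmpl
        if (config$background_sub_rate > 0) {
          hit <- free_pos[stats::runif(length(free_pos)) <
                            config$background_sub_rate]
          if (length(hit)) {
            rec[hit] <- vapply(rec[hit], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1L)
            }, character(1))
          }
        }
        id <- sprintf("%s_%04d", tx$label, start_i + i)
        ids <- c(ids, id)
        seqs <- c(seqs, paste(rec, collapse = ""))
        truth <- c(truth, stats::setNames(tx$label, id))
        abund <- c(abund, stats::setNames(tx$weight, id))
        lineages <- c(lineages, tx$lineage)
      }
    }
    lin <- as.data.frame(
      do.call(rbind, lapply(paste0("x ", lineages), parse_lineage)),
      stringsAsFactors = FALSE)
    colnames(lin) <- canonical_ranks()
    refset <- ref_set(ids, seqs, lin, is_aligned = TRUE)
    structure(list(refset = refset, truth = truth, abundances = abund,
                   layout = lay, config = config),
              class = "mock_community")
  })
}

#' @export
print.mock_community <- function(x, ...) {
  cat(sprintf("<mock_community> %d record(s), %d taxa, seed %d\n",
              length(x$refset), length(unique(x$truth)), x$config$seed))
  invisible(x)
}

#' Simulate reads from a mock community
#'
#' Draws reads from the nested amplicons of amplifiable records with
#' probability proportional to template abundance, then applies uniform
#' substitution errors per base (no homopolymer indels: the simulated
#' reads sit downstream of denoising). Read ids carry no truth
#' information; the truth mapping is returned (and optionally written)
#' as a sidecar table.
#'
#' @param community a [generate_reference_set()] result.
#' @param strategy a [nested_strategy()].
#' @param n_reads number of reads.
#' @param per_base_error substitution probability per base, in `[0, 1]`.
#' @param seed integer seed for sampling and errors.
#' @return list with `reads` (named character vector, names = read ids)
#'   and `truth` (data.frame: read_id, record_id, taxon).
#' @export
simulate_reads <- function(community, strategy, n_reads = 10000L,
                           per_base_error = 0.005, seed = 1L) {
  stopifnot(inherits(community, "mock_community"),
            inherits(strategy, "nested_strategy"),
            per_base_error >= 0, per_base_error <= 1)
  n_reads <- as.integer(n_reads)
  refset <- community$refset
  amps <- lapply(seq_along(refset$id), function(i) {
    a <- semi_nested(refset$ungapped[i], strategy, refset$id[i])
    if (nrow(a) == 0L) NULL else a[1L, , drop = FALSE]
  })
  ok <- !vapply(amps, is.null, logical(1))
  if (n_reads > 0L && !any(ok)) {
    stop_user("no amplifiable record in the community")
  }
  amp_ids <- refset$id[ok]
  amp_seqs <- vapply(amps[ok], `[[`, character(1), "seq")
  w <- community$abundances[amp_ids]
  if (sum(w) <= 0) stop_user("amplifiable records all have zero abundance")

  with_seed(seed, {
    pick <- sample.int(length(amp_ids), n_reads, replace = TRUE,
                       prob = w / sum(w))
    reads <- amp_seqs[pick]
    if (per_base_error > 0 && n_reads > 0L) {
      reads <- vapply(reads, function(s) {
        ch <- seq_chars(s)
        hit <- which(stats::runif(length(ch)) < per_base_error)
        if (length(hit)) {
          ch[hit] <- vapply(ch[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    read_ids <- sprintf("read_%06d", seq_len(n_reads))
    list(reads = stats::setNames(reads, read_ids),
         truth = data.frame(read_id = read_ids,
                            record_id = amp_ids[pick],
                            taxon = unname(community$truth[amp_ids[pick]]),
                            stringsAsFactors = FALSE))
  })
}

#' Write simulated reads and their truth sidecar
#'
#' @param sim result of [simulate_reads()].
#' @param fasta_path output FASTA of reads.
#' @param truth_path output two-column TSV (read_id TAB taxon).
#' @return invisible NULL.
#' @export
write_reads <- function(sim, fasta_path, truth_path) {
  write_lines_atomic(as.vector(rbind(paste0(">", names(sim$reads)),
                                     unname(sim$reads))), fasta_path)
  write_lines_atomic(paste(sim$truth$read_id, sim$truth$taxon, sep = "\t"),
                     truth_path)
  invisible(NULL)
}

#' Expected composition of a mock community
#'
#' Abundance-weighted taxon proportions among amplifiable records — the
#' ground truth that read simulation should recover up to multinomial
#' sampling noise.
#'
#' @param community a [generate_reference_set()] result.
#' @param strategy a [nested_strategy()].
#' @param rank one of [canonical_ranks()].
#' @return a `community_profile` (see [taxon_amplification_summary()]).
#' @export
truth_composition <- function(community, strategy, rank = "phylum") {
  stopifnot(inherits(community, "mock_community"))
  taxon_amplification_summary(community$refset, strategy, rank,
                              weights = community$abundances)
}
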