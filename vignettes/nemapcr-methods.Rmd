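---
title: "Modeling a nematode-selective semi-nested SSU amplification assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a nematode-selective semi-nested SSU amplification assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemapcr)
```

## The problem

Soil nematode communities are profiled by sequencing a fragment of the
small-subunit (SSU, 18S) rRNA gene, but widely used SSU primer pairs such
as NF1/18Sr2b co-amplify fungi, plants and other eukaryotes that dominate
total soil DNA; without a laborious nematode-enrichment step, only a small
minority of reads come from nematodes. A nematode/metazoan-selective
forward primer (NemF) used in a semi-nested scheme — a pre-amplification
with NemF + 18Sr2b followed by re-amplification with tagged NF1 + 18Sr2b
inside the first-round product — suppresses fungal and plant templates
while keeping the final amplicon short enough for amplicon sequencing.

`nemapcr` models this assay *in silico*: it scores primer-template binding
with an explicit 3'-terminal mismatch rule, tabulates per-position primer
conservation across taxon groups, predicts single-pair and semi-nested
amplicons with adapter/MID tag arithmetic, and generates seeded mock
communities so the whole pipeline can be exercised and tested without any
external reference download.

## The binding model

A primer base and a template base match when their IUPAC expansion sets
intersect (`R` matches `A` or `G`; a degenerate template base matches a
primer base if any of its readings would). A template `N` is controlled by
a policy switch: `"permissive-match"` (default; `N` is usually a read
ambiguity, not biology) or `"count-as-mismatch"`.

A placement of a primer of length $k$ on a template is accepted when

* total mismatches $\le$ `max_mismatches`, and
* mismatches within the last `three_prime_window` primer positions
  (counted from the 3' end) $\le$ `max_three_prime_mismatches`.

Defaults are `max_mismatches = 2`, `three_prime_window = 3`,
`max_three_prime_mismatches = 0`. The rationale: the selectivity of NemF
is carried by 3'-terminal mismatches to fungal and plant templates, where
a single mismatch effectively blocks polymerase extension, while a couple
of body mismatches are routinely tolerated at moderate annealing
stringency. No melting-temperature or duplex free-energy model is used;
the two PCR rounds' different annealing temperatures can only be expressed
as different `match_params()` per round, which we document as a
limitation rather than hide behind a pseudo-thermodynamic score.

Reverse primers are given 5'→3' and matched as their reverse complement
on the template plus strand; mismatch vectors are always reported in
primer orientation so the 3' window refers to the primer's own 3' end.
Coordinates are 1-based and inclusive throughout, the base-R/Bioconductor
convention, so `end - start + 1` is always a length; rendered tables
number primer positions 1-based as well.

## Conservation and consensus tables

For a primer located in an aligned reference set
(`locate_primer_site()` takes each record's best site — fewest
mismatches, leftmost on ties — and returns the modal alignment-column
run, flagging records that disagree rather than dropping them), two
summaries are computed per taxon group:

* **Conservation**: per primer position, the percentage of sequences whose
  residue IUPAC-matches the *primer* base, among sequences with a non-gap
  residue at that column. This is conservation *relative to the primer*,
  not the frequency of the modal base — the reading under which a
  position with 81 of 100 matching residues prints as 81. Gapped residues
  are excluded from numerator and denominator: an indel is not evidence
  about base identity. Percentages are rounded half-up to integers for
  display.
* **Consensus (dot notation)**: per position, the most frequent non-gap
  residue if its frequency reaches `majority_threshold` (default 0.5);
  on a tie, or when nothing reaches the threshold, the minimal IUPAC code
  covering all residues at frequency ≥ 0.25 (a 50/50 A/G split renders
  as R). A position is printed as a dot exactly when the consensus base
  IUPAC-matches the primer base, so diagnostic substitutions stand out —
  the fungal/plant pattern at the NemF site is
  `....G........C....G`, with the final G sitting on the primer's
  3'-terminal base.

Whether the in-group percentage row should count gapped sequences in its
denominator, and whether a "metazoan" out-group excludes nematodes, are
choices the data sources leave open; both are left to the caller
(denominator choice is fixed to non-gap counts, group membership is
whatever `subset_by_taxon()` is asked for).

## Amplicon prediction and the semi-nested strategy

`find_amplicons()` pairs every passing forward site with every passing
downstream reverse site and keeps products within `[min_product,
max_product]` (default 100–2000 nt — wide enough for SSU-scale inserts,
tight enough to exclude degenerate pairings). `semi_nested()` runs the
outer pair, then re-amplifies each round-1 product with the inner pair,
mapping nested coordinates back to the original template; the shared
reverse primer is enforced at strategy construction. Amplification is
binary per template: cycle counts and efficiencies are deliberately not
modeled, and community summaries count amplifiable *templates*, not
products, to avoid double counting. Only plus-strand templates are
scanned for the forward primer, since curated reference sets are
orientation-normalized.

Tag decoration follows the fusion-primer construction used for
multiplexed pyrosequencing: `adapter_fwd + MID + product +
revcomp(adapter_rev)`, with a mandatory 10-nt MID. With the packaged
25-nt adapters the tagged length always exceeds the untagged product by
exactly 60 nt, so the 350-nt inner product of the default simulator
geometry reads out at 410 nt — consistent with an expected gel size of
roughly 420 bp, whose printed value plausibly includes the MID and both
adapters. The 22 packaged MIDs are synthetic stand-ins (distinct 10-mers
chosen here); the vendor tags used with the original assay were never
published.

## The mock-community generator

`generate_reference_set()` builds one seeded SSU-like base template:

```
5' flank (100 nt) | NemF site | spacer (30 nt) | NF1 site |
insert (305 nt) | revcomp(18Sr2b site) | 3' flank (100 nt)
```

so the outer and inner products exist by construction and the inner
product is 24 + 305 + 21 = 350 nt. Each taxon applies its
`taxon_signature()` substitutions exactly (positions are primer
positions; reverse-primer signatures are complemented onto the plus
strand), and each record receives independent background substitutions
outside all primer sites (default rate 0.02 per site, a plausible
within-group SSU divergence at this scale). Background noise never
touches primer sites: this keeps the specificity mechanism and the noise
model separable, which is what makes the exclusion tests sharp. All
records share one gap-free coordinate system, so the simulated set
doubles as a trivial alignment for the conservation profiler.

What the simulator does *not* emulate: real SSU alignments with indels
and length heterogeneity, chimeras, homopolymer (flowgram) errors,
primer-site microheterogeneity beyond the configured signatures, and
amplification bias. Read simulation draws templates
abundance-proportionally from amplifiable records and applies uniform
substitution errors only (default 0.005 per base, i.e. post-denoising
quality). Passing end-to-end tests therefore demonstrate the internal
consistency of the matching, nesting and counting machinery under known
truth — not robustness to the full error structure of environmental
sequencing data.

## Numerical and design choices

* Best-site ties break to the leftmost start; scan output is sorted by
  (mismatch count, start) for determinism.
* Percentages round half-up; a position with no informative residue
  reports NA and renders as `-`.
* `U` is silently normalized to `T`, `.` gaps to `-`, and case to upper
  on every input path.
* Empty scan results and empty subsets are values, not errors; errors are
  reserved for malformed inputs and impossible configurations (duplicate
  ids, unequal aligned lengths, a signature replacing a base with
  itself, nested rounds with different reverse primers, a MID that is
  not 10 nt).
* All randomness flows through explicit seeds; the generator and read
  simulator are byte-reproducible given a seed.

## Problem sizes

The shipped tests and the acceptance script run on desk-scale instances
chosen to exercise every code path while staying fast: 200 random
template/primer/parameter triples (templates ≤ 1 kb) for the brute-force
scan cross-check, reference sets of 100–181 records for the
specificity-table mechanics, 30 signature-blocked templates for the
exclusion checks, and 10,000 simulated reads from a 54-record,
four-taxon mock community for composition recovery, judged against
3-sigma multinomial bounds. Empirical read-set compositions from field
studies depend on denoising, OTU clustering and reference-database
classification pipelines that are outside this package's scope, and are
not reproduced here.
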