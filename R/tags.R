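# Tagged-primer decoration for pyrosequencing-style multiplexing: the
# forward fusion primer is adapter + 10-nt MID + template primer, the
# reverse fusion primer is adapter + template primer (no MID), so a
# tagged product gains adapter_fwd + MID on its 5' side and the reverse
# complement of adapter_rev on its 3' side: 25 + 10 + 25 = 60 nt in the
# packaged scheme.

#' Define a tag scheme
#'
#' @param adapter_fwd,adapter_rev non-empty adapter sequences (5'->3' as
#'   synthesized on the fusion primers).
#' @param mid a 10-nt multiplex identifier placed between the forward
#'   adapter and the forward template primer.
#' @return object of class `tag_scheme`.
#' @export
tag_scheme <- function(adapter_fwd, mid, adapter_rev) {
  adapter_fwd <- normalize_seq(adapter_fwd)
  adapter_rev <- normalize_seq(adapter_rev)
  mid <- normalize_seq(mid)
  if (!nzchar(adapter_fwd) || !nzchar(adapter_rev)) {
    stop_user("adapters must be non-empty")
  }
  if (nchar(mid) != 10L) {
    stop_user("MID must be exactly 10 nt (got ", nchar(mid), ")")
  }
  for (s in c(adapter_fwd, mid, adapter_rev)) seq_mask(s, "tag scheme sequence")
  structure(list(adapter_fwd = adapter_fwd, mid = mid,
                 adapter_rev = adapter_rev),
            class = "tag_scheme")
}

#' The packaged tag scheme
#'
#' The two 25-nt pyrosequencing adapters of the published fusion primers
#' (forward CGTATCGCCTCCCTCGCGCCATCAG, reverse CTATGCGCCTTGCCAGCCCGCTCAG)
#' with one of the packaged MIDs.
#'
#' @param mid 10-nt MID, default the first entry of [default_mids()].
#' @return a [tag_scheme()].
#' @export
default_tag_scheme <- function(mid = default_mids()[1]) {
  tag_scheme("CGTATCGCCTCCCTCGCGCCATCAG", mid, "CTATGCGCCTTGCCAGCCCGCTCAG")
}

#' The packaged MID list
#'
#' Twenty-two distinct 10-nt multiplex identifiers, one per sample of a
#' 22-soil design. These are synthetic stand-ins chosen for this package
#' (the vendor MIDs used in the original study were not published); they
#' are also shipped as `inst/extdata/mids_synthetic.tsv`.
#'
#' @return character vector of 22 tags, named MID01..MID22.
#' @export
default_mids <- function() {
  tags <- c(
    "ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG",
    "ATCAGACACG", "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC",
    "TAGTATCAGC", "TCTCTATGCG", "TGATACGTCT", "TACTGAGCTA",
    "CATAGTAGTG", "CGAGAGATAC", "ATACGACGTA", "TCACGTACTA",
    "CGTCTAGTAC", "TCTACGTAGC", "TGTACTACTC", "ACGACTACAG",
    "CGTAGACTAG", "TACGAGTATG")
  stats::setNames(tags, sprintf("MID%02d", seq_along(tags)))
}

#' Decorate amplicons with adapters and a MID
#'
#' Applies the fusion-primer construction to predicted (inner-round)
#' amplicons: tagged sequence = adapter_fwd + MID + amplicon + revcomp
#' (adapter_rev). Tagged length always exceeds the untagged length by
#' the summed adapter and MID lengths (60 nt for the packaged scheme),
#' so a 350-nt insert-round product reads out at 410 nt and a 360-nt
#' one at about 420 nt.
#'
#' @param amplicons data.frame from [find_amplicons()] or [semi_nested()].
#' @param scheme a [tag_scheme()].
#' @return the amplicon data.frame with added columns `tagged_seq` and
#'   `tagged_length`.
#' @export
tag_amplicon <- function(amplicons, scheme) {
  stopifnot(is.data.frame(amplicons), inherits(scheme, "tag_scheme"))
  extra <- nchar(scheme$adapter_fwd) + nchar(scheme$mid) +
    nchar(scheme$adapter_rev)
  amplicons$tagged_seq <- paste0(scheme$adapter_fwd, scheme$mid,
                                 amplicons$seq, revcomp(scheme$adapter_rev))
  amplicons$tagged_length <- amplicons$length + extra
  amplicons
}
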