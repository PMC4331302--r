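nemf_18s_pair <- function(params = match_params(),
                          min_product = 100, max_product = 2000) {
  p <- default_primers()
  primer_pair(p$NemF, p$`18Sr2b`, params, min_product, max_product)
}

nf1_18s_pair <- function(params = match_params(),
                         min_product = 100, max_product = 2000) {
  p <- default_primers()
  primer_pair(p$NF1, p$`18Sr2b`, params, min_product, max_product)
}

# template with exact NemF at `fwd_at` and the 18Sr2b footprint ending at
# fwd_at + span - 1, i.e. a product of length `span`.
simple_template <- function(span = 400, fwd_at = 51, total = 520) {
  p <- default_primers()
  rev_site <- revcomp(p$`18Sr2b`$seq)
  tpl <- random_template(total)
  tpl <- plant_site(tpl, p$NemF$seq, fwd_at)
  plant_site(tpl, rev_site, fwd_at + span - nchar(rev_site))
}

test_that("a constructed template yields one product with exact coordinates", {
  set.seed(41)
  tpl <- simple_template(span = 400, fwd_at = 51)
  amps <- find_amplicons(tpl, nemf_18s_pair(), "t1")
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$start, 51L)
  expect_equal(amps$end, 450L)
  expect_equal(amps$length, 400L)
  expect_equal(amps$seq, substring(tpl, 51, 450))
  expect_true(startsWith(amps$seq, default_primers()$NemF$seq))
  expect_true(endsWith(amps$seq, revcomp(default_primers()$`18Sr2b`$seq)))
})

test_that("the fungal 3'-signature abolishes amplification under a strict window", {
  set.seed(42)
  tpl <- simple_template()
  blocked <- plant_site(tpl, "GGGGGAGTATGGTCGCAAG", 51)
  expect_equal(nrow(find_amplicons(blocked,
                                   nemf_18s_pair(match_params(3, 3, 0)))), 0L)
  # with the 3' veto lifted the same template amplifies
  expect_gt(nrow(find_amplicons(blocked,
                                nemf_18s_pair(match_params(3, 3, 1)))), 0L)
})

test_that("multiple forward sites each pair with the downstream reverse site", {
  p <- default_primers()
  set.seed(43)
  tpl <- random_template(800)
  tpl <- plant_site(tpl, p$NemF$seq, 41)
  tpl <- plant_site(tpl, p$NemF$seq, 151)
  tpl <- plant_site(tpl, revcomp(p$`18Sr2b`$seq), 680)
  amps <- find_amplicons(tpl, nemf_18s_pair(), "t")
  expect_equal(nrow(amps), 2L)
  expect_equal(sort(amps$start), c(41L, 151L))
  expect_equal(unique(amps$end), 700L)
})

test_that("find_amplicons agrees with the exhaustive placement oracle", {
  set.seed(44)
  p <- default_primers()
  for (rep in 1:20) {
    L <- sample(300:900, 1)
    tpl <- random_template(L)
    tpl <- plant_site(tpl, p$NemF$seq, sample(20:80, 1))
    tpl <- plant_site(tpl, revcomp(p$`18Sr2b`$seq), sample(200:(L - 30), 1))
    mm <- sample(0:2, 1)
    got <- find_amplicons(tpl, nemf_18s_pair(match_params(mm, 3, 0)))
    exp <- oracle_amplicons(tpl, p$NemF$seq, p$`18Sr2b`$seq, mm, 3, 0)
    expect_equal(got$start, exp$start, info = paste("rep", rep))
    expect_equal(got$end, exp$end, info = paste("rep", rep))
  }
})

test_that("product length bounds and pair validation are enforced", {
  expect_error(nemf_18s_pair(min_product = 30), "summed primer lengths")
  expect_error(nemf_18s_pair(min_product = 900, max_product = 800),
               "exceeds max_product")
  set.seed(45)
  tpl <- simple_template(span = 400)
  expect_equal(nrow(find_amplicons(tpl, nemf_18s_pair(max_product = 399))), 0L)
  expect_equal(nrow(find_amplicons(tpl, nemf_18s_pair(min_product = 401))), 0L)
})

test_that("semi-nested products are bounded by the inner primer and contained", {
  p <- default_primers()
  comm <- fixture_community(seed = 51, n_nem = 3, n_fun = 2, n_tar = 1,
                            n_rot = 1, bg = 0)
  strat <- default_nested_strategy()
  tpl <- comm$refset$ungapped[1]
  nested <- semi_nested(tpl, strat, "nem1")
  expect_equal(nrow(nested), 1L)
  expect_equal(nested$round, "nested")
  expect_equal(nested$start, comm$layout$starts[["NF1"]])
  expect_equal(nested$length,
               24L + comm$config$insert_length + 21L)  # NF1 + insert + 18Sr2b
  expect_true(startsWith(nested$seq, p$NF1$seq))
  # containment in the round-1 product
  expect_true(nested$start >= nested$parent_start &&
                nested$end <= nested$parent_end)
})

test_that("3'-blocked templates nest to zero while the inner pair alone amplifies", {
  comm <- fixture_community(seed = 52, bg = 0)
  strat <- default_nested_strategy()
  fungal <- comm$refset$ungapped[comm$truth == "Fungi"][1]
  expect_equal(nrow(semi_nested(fungal, strat)), 0L)
  inner_alone <- find_amplicons(fungal, nf1_18s_pair())
  expect_gt(nrow(inner_alone), 0L)
})

test_that("semi-nested requires a shared reverse primer", {
  p <- default_primers()
  expect_error(
    nested_strategy(primer_pair(p$NemF, p$`18Sr2b`),
                    primer_pair(p$NF1, p$NemF,
                                min_product = nchar(p$NF1$seq) +
                                  nchar(p$NemF$seq))),
    "identical outer and inner")
})

test_that("a template without the outer reverse site yields nothing nested", {
  p <- default_primers()
  set.seed(46)
  tpl <- plant_site(random_template(500), p$NemF$seq, 51)
  tpl <- plant_site(tpl, p$NF1$seq, 101)
  expect_equal(nrow(semi_nested(tpl, default_nested_strategy())), 0L)
})

test_that("relaxing match parameters never removes nested amplicons", {
  comm <- fixture_community(seed = 53, n_nem = 5, n_fun = 3, n_tar = 2,
                            n_rot = 2, bg = 0.03)
  tight <- default_nested_strategy(match_params(1, 3, 0), match_params(1, 3, 0))
  loose <- default_nested_strategy(match_params(3, 3, 1), match_params(3, 3, 1))
  for (i in seq_along(comm$refset$id)) {
    a1 <- semi_nested(comm$refset$ungapped[i], tight)
    a2 <- semi_nested(comm$refset$ungapped[i], loose)
    expect_true(all(a1$start %in% a2$start))
    expect_gte(nrow(a2), nrow(a1))
  }
})

test_that("tag decoration adds exactly the adapter and MID lengths", {
  set.seed(47)
  scheme <- default_tag_scheme()
  tpl350 <- simple_template(span = 350, fwd_at = 51)
  amp <- find_amplicons(tpl350, nemf_18s_pair())
  tagged <- tag_amplicon(amp, scheme)
  expect_equal(tagged$tagged_length, 410L)
  expect_equal(nchar(tagged$tagged_seq), 410L)
  expect_equal(tagged$tagged_seq,
               paste0(scheme$adapter_fwd, scheme$mid, amp$seq,
                      revcomp(scheme$adapter_rev)))

  tpl360 <- simple_template(span = 360, fwd_at = 51)
  amp2 <- find_amplicons(tpl360, nemf_18s_pair())
  expect_equal(tag_amplicon(amp2, scheme)$tagged_length, 420L)

  expect_error(tag_scheme("CGTATCGCCTCCCTCGCGCCATCAG", "",
                          "CTATGCGCCTTGCCAGCCCGCTCAG"), "10 nt")
  expect_error(tag_scheme("", "ACGAGTGCGT", "CTATGCGCCTTGCCAGCCCGCTCAG"),
               "non-empty")
})

test_that("packaged MIDs are 22 distinct 10-nt tags matching the shipped file", {
  mids <- default_mids()
  expect_length(mids, 22L)
  expect_equal(anyDuplicated(mids), 0L)
  expect_true(all(nchar(mids) == 10L))
  shipped <- read.table(system.file("extdata", "mids_synthetic.tsv",
                                    package = "nemapcr"),
                        sep = "\t", comment.char = "#",
                        col.names = c("name", "mid"))
  expect_equal(shipped$mid, unname(mids))
})

test_that("amplification summary counts templates per taxon with weights", {
  sig <- taxon_signature("NemF", c("5" = "G", "14" = "C", "19" = "G"))
  cfg <- sim_config(list(
    sim_taxon("Nematoda", 60),
    sim_taxon("Fungi", 20, sig, lineage = "Fungi;Fungi"),
    sim_taxon("Plantae", 10, sig, lineage = "Plantae;Plantae"),
    sim_taxon("Tardigrada", 10)
  ), background_sub_rate = 0, seed = 55)
  comm <- generate_reference_set(cfg)
  summ <- taxon_amplification_summary(comm$refset, default_nested_strategy(),
                                      "phylum")
  expect_equal(summ$n_templates, 100L)
  expect_equal(summ$n_amplifiable, 70L)
  expect_equal(summ$proportions[["Nematoda"]], 6 / 7)
  expect_equal(summ$proportions[["Tardigrada"]], 1 / 7)
  expect_equal(sum(summ$proportions), 1)
  expect_equal(summ$amplifiable_fraction[["Fungi"]], 0)
  expect_equal(summ$amplifiable_fraction[["Plantae"]], 0)
  expect_equal(summ$amplifiable_fraction[["Nematoda"]], 1)

  # single-taxon community collapses to a single full share
  one <- generate_reference_set(sim_config(list(sim_taxon("Nematoda", 4)),
                                           background_sub_rate = 0, seed = 56))
  s1 <- taxon_amplification_summary(one$refset, default_nested_strategy())
  expect_equal(s1$proportions, c(Nematoda = 1))

  # zero amplifiable templates is a valid (empty) profile, not an error
  blocked <- generate_reference_set(sim_config(
    list(sim_taxon("Fungi", 3, sig, lineage = "Fungi;Fungi")),
    background_sub_rate = 0, seed = 57))
  s0 <- taxon_amplification_summary(blocked$refset, default_nested_strategy())
  expect_equal(s0$n_amplifiable, 0L)
  expect_length(s0$proportions, 0L)
})
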