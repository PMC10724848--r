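test_that("generation is a pure function of the config", {
  cfg <- sim_config(seed = 3, n_templates = 80, planted_dup_rate = 0.2, barcode_n = 2)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(as.character(ref1), as.character(ref2))
  s1 <- simulate_alignments(cfg, ref1)
  s2 <- simulate_alignments(cfg, ref2)
  expect_identical(s1$sam, s2$sam)
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the stream
  s3 <- simulate_alignments(sim_config(
    seed = 4, n_templates = 80,
    planted_dup_rate = 0.2, barcode_n = 2
  ), ref1)
  expect_false(identical(s1$sam$pos, s3$sam$pos))
})

test_that("fixtures are valid name-grouped SAM with truthful structure", {
  cfg <- sim_config(seed = 13, n_templates = 200, planted_dup_rate = 0.3)
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(cfg, ref)
  expect_silent(check_name_grouped(sim$sam$qname))
  # truth covers every template exactly once
  expect_setequal(unique(sim$sam$qname), sim$truth$qname)
  # the first occurrence of each fragment is the nonduplicate
  first <- !duplicated(sim$truth$fragment_id)
  expect_identical(sim$truth$is_planted_dup, !first)
  # copies are byte-identical to their original apart from QNAME
  dup_rows <- sim$truth[sim$truth$is_planted_dup, ]
  if (nrow(dup_rows)) {
    orig_qn <- sim$truth$qname[match(dup_rows$fragment_id[1], sim$truth$fragment_id)]
    a <- sim$sam[sim$sam$qname == orig_qn, -1]
    b <- sim$sam[sim$sam$qname == dup_rows$qname[1], -1]
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
  # planted rate 0 -> no duplicate relations at all
  cfg0 <- sim_config(seed = 13, n_templates = 100, planted_dup_rate = 0)
  sim0 <- simulate_alignments(cfg0, simulate_reference(cfg0))
  expect_false(any(sim0$truth$is_planted_dup))
})

test_that("planted conversions match the declared strand chemistry", {
  cfg <- sim_config(
    seed = 23, n_contigs = 1, n_templates = 150, planted_dup_rate = 0,
    paired_frac = 1, clip_prob = 0, conversion_rate = 0.9,
    methylation_rate = 0, both_unmapped_rate = 0, one_unmapped_rate = 0,
    secondary_rate = 0
  )
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(cfg, ref)
  opened <- open_reference(ref)
  prim <- sim$sam[bitwAnd(sim$sam$flag, 0x900L) == 0L, ]
  conv <- t(vapply(seq_len(nrow(prim)), function(i) {
    count_conversions(prim$rname[i], prim$pos[i], prim$cigar[i], prim$seq[i], opened)
  }, numeric(2)))
  strand <- sim$truth$strand[match(prim$qname, sim$truth$qname)]
  # top-strand templates show C->T on both mates, bottom-strand G->A
  expect_true(all(conv[strand == "TOP", "ct"] > conv[strand == "TOP", "ga"]))
  expect_true(all(conv[strand == "BOTTOM", "ga"] > conv[strand == "BOTTOM", "ct"]))
})

test_that("reference precondition is enforced", {
  expect_error(
    simulate_reference(sim_config(contig_length = 50, read_length = 100)),
    "read_length"
  )
})

test_that("the brute-force oracle restates the duplicate rule", {
  # three identical templates -> the first survives, two are marked
  sam <- sam_from_text(
    pe_pair_lines("o1"), pe_pair_lines("o2"), pe_pair_lines("o3")
  )
  expect_setequal(
    oracle_mark(sam, bin_width = 1000, padding = 100), c("o2", "o3")
  )
  # two templates differing only in barcode -> none marked under auto
  samb <- sam_from_text(
    pe_pair_lines("b1", extra_tags = "CB:Z:AAA"),
    pe_pair_lines("b2", extra_tags = "CB:Z:CCC")
  )
  expect_equal(
    oracle_mark(samb, barcode = "auto", bin_width = 1000, padding = 100),
    character()
  )
  # two templates differing only in strand class: wgs collapses them
  sams <- sam_from_text(
    pe_pair_lines("s1", tag = "YD:Z:f"), pe_pair_lines("s2", tag = "YD:Z:r")
  )
  expect_equal(
    oracle_mark(sams, mode = "bisulfite", bin_width = 1000, padding = 100),
    character()
  )
  expect_equal(
    oracle_mark(sams, mode = "wgs", bin_width = 1000, padding = 100), "s2"
  )
})

test_that("engine and oracle agree across randomized configurations", {
  set.seed(77)
  for (k in 1:12) {
    cfg <- sim_config(
      seed = 700 + k,
      n_contigs = sample(1:3, 1),
      contig_length = 20000,
      n_templates = sample(c(40, 120, 250), 1),
      planted_dup_rate = sample(c(0, 0.15, 0.45), 1),
      strand_mix = stats::runif(1, 0.2, 0.8),
      paired_frac = stats::runif(1, 0.3, 1),
      clip_prob = stats::runif(1, 0, 0.4),
      barcode_n = sample(c(0L, 3L), 1),
      tag_frac = sample(c(0.6, 1), 1),
      secondary_rate = stats::runif(1, 0, 0.15)
    )
    ref <- simulate_reference(cfg)
    sim <- simulate_alignments(cfg, ref)
    bcmode <- if (cfg$barcode_n > 0) "auto" else "off"
    for (mode in c("bisulfite", "wgs")) {
      eng <- mark_duplicates(sim$sam,
        reference = ref, mode = mode,
        barcode = bcmode, bin_width = 3e4, padding = 500
      )
      ora <- oracle_mark(sim$sam,
        reference = ref, mode = mode,
        barcode = bcmode, bin_width = 3e4, padding = 500
      )
      expect_setequal(marked_qnames(eng), ora)
    }
  }
})

test_that("co-located strand pairs behave like distinct molecules", {
  sp <- simulate_strand_pairs(50, seed = 9)
  bs <- mark_duplicates(sp$sam, bin_width = 1e4, padding = 200)
  expect_equal(bs$stats$templates_marked_dup, 0L)
  wgs <- mark_duplicates(sp$sam, mode = "wgs", bin_width = 1e4, padding = 200)
  t <- tidy(wgs)
  marked_per_pair <- tapply(
    t$duplicate, sp$pairs$pair[match(t$qname, sp$pairs$qname)], sum
  )
  expect_true(all(marked_per_pair == 1L))
})
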