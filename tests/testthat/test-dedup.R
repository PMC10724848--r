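test_that("first occurrence wins; later identical templates are marked", {
  sam <- sam_from_text(
    pe_pair_lines("t1"), pe_pair_lines("t2"), pe_pair_lines("t3"),
    sam_line("u1", 0L, pos = 300L, tags = "YD:Z:f")
  )
  res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  expect_equal(marked_qnames(res), c("t2", "t3"))
  # every record of a marked template carries 0x400; none of the first
  flags <- split(res$records$flag, res$records$qname)
  expect_true(all(bitwAnd(flags$t2, 0x400L) != 0L))
  expect_true(all(bitwAnd(flags$t3, 0x400L) != 0L))
  expect_true(all(bitwAnd(c(flags$t1, flags$u1), 0x400L) == 0L))
})

test_that("co-located opposite-strand templates are kept apart in bisulfite mode only", {
  sam <- sam_from_text(
    pe_pair_lines("top", tag = "YD:Z:f"),
    pe_pair_lines("bot", tag = "YD:Z:r")
  )
  bs <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  expect_equal(marked_qnames(bs), character())
  wgs <- mark_duplicates(sam, mode = "wgs", bin_width = 1000, padding = 100)
  expect_equal(marked_qnames(wgs), "bot")
})

test_that("the verdict propagates to secondary and supplementary records", {
  grp <- function(qn) {
    c(
      pe_pair_lines(qn),
      sam_line(qn, 2195L, pos = 390L, cigar = "25M25S", tags = "YD:Z:f"),
      sam_line(qn, 355L, pos = 350L, tags = "YD:Z:f")
    )
  }
  sam <- sam_from_text(grp("a"), grp("b"))
  res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  flags <- split(res$records$flag, res$records$qname)
  expect_true(all(bitwAnd(flags$b, 0x400L) != 0L)) # all four records
  expect_true(all(bitwAnd(flags$a, 0x400L) == 0L))
  # and the secondary/supplementary records did not influence the decision:
  # removing them changes nothing about the marked set
  sam2 <- sam_from_text(pe_pair_lines("a"), pe_pair_lines("b"))
  expect_equal(
    marked_qnames(mark_duplicates(sam2, bin_width = 1000, padding = 100)), "b"
  )
})

test_that("pre-existing duplicate flags are cleared and recomputed", {
  sam <- sam_from_text(
    sam_line("x", 1024L, pos = 50L, tags = "YD:Z:f"), # stale mark, unique read
    sam_line("y", 0L, pos = 70L, tags = "YD:Z:f")
  )
  res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  expect_equal(res$records$flag, c(0L, 0L))
})

test_that("marking is idempotent: rerunning on output changes no flags", {
  cfg <- sim_config(seed = 21, n_templates = 200, planted_dup_rate = 0.3)
  sim <- simulate_alignments(cfg, simulate_reference(cfg))
  r1 <- mark_duplicates(sim$sam, bin_width = 1e5, padding = 1000)
  r2 <- mark_duplicates(r1$records, bin_width = 1e5, padding = 1000)
  expect_identical(r2$records$flag, r1$records$flag)
  expect_identical(r2$stats, r1$stats)
})

test_that("bisulfite-mode marks are a subset of wgs-mode marks", {
  cfg <- sim_config(
    seed = 31, n_templates = 300, planted_dup_rate = 0.2,
    tag_frac = 0.8
  )
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(cfg, ref)
  bs <- marked_qnames(mark_duplicates(sim$sam,
    reference = ref,
    bin_width = 1e5, padding = 1000
  ))
  wgs <- marked_qnames(mark_duplicates(sim$sam,
    mode = "wgs",
    bin_width = 1e5, padding = 1000
  ))
  expect_true(all(bs %in% wgs))
})

test_that("the marked count is invariant under permuting template order", {
  cfg <- sim_config(seed = 41, n_templates = 150, planted_dup_rate = 0.4)
  sim <- simulate_alignments(cfg, simulate_reference(cfg))
  res1 <- mark_duplicates(sim$sam, bin_width = 1e5, padding = 1000)
  # permute template blocks, keeping within-group order
  set.seed(99)
  tid <- check_name_grouped(sim$sam$qname)
  perm <- sample(max(tid))
  ord <- order(match(tid, perm))
  shuffled <- sim$sam[ord, ]
  attr(shuffled, "header") <- sam_header(sim$sam)
  res2 <- mark_duplicates(shuffled, bin_width = 1e5, padding = 1000)
  expect_equal(
    res2$stats$templates_marked_dup,
    res1$stats$templates_marked_dup
  )
  # the partition is identical: each duplicate class keeps one unmarked
  k1 <- table(res1$templates$sig_key, res1$templates$strand)
  k2 <- table(res2$templates$sig_key, res2$templates$strand)
  expect_equal(k1[order(rownames(k1)), ], k2[order(rownames(k2)), ])
})

test_that("both-unmapped pairs pass through untouched and are counted", {
  sam <- sam_from_text(
    sam_line("u", 77L, rname = "*", pos = 0L, mapq = "0", cigar = "*"),
    sam_line("u", 141L, rname = "*", pos = 0L, mapq = "0", cigar = "*"),
    pe_pair_lines("m1"), pe_pair_lines("m2")
  )
  res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  expect_equal(res$stats$pairs_both_unmapped_passed, 1L)
  expect_equal(res$passthrough, "u")
  expect_equal(res$records$flag[1:2], c(77L, 141L))
  expect_equal(marked_qnames(res), "m2")
})

test_that("one-mate-unmapped templates deduplicate on the mapped mate", {
  half <- function(qn, pos) {
    c(
      sam_line(qn, 73L,
        pos = pos, rnext = "=", pnext = pos,
        tags = "YD:Z:f"
      ), # paired, mate unmapped, R1 mapped forward
      sam_line(qn, 133L,
        rname = "chr1", pos = pos, mapq = "0", cigar = "*",
        rnext = "=", pnext = pos, tags = "YD:Z:f"
      )
    )
  }
  sam <- sam_from_text(
    half("h1", 50L), half("h2", 50L),
    sam_line("se", 0L, pos = 50L, tags = "YD:Z:f") # true SE at same spot
  )
  res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  # h2 duplicates h1, but the single-end read never collides with them
  expect_equal(marked_qnames(res), "h2")
  t <- tidy(res)
  expect_equal(t$is_paired[t$qname == "h1"], TRUE)
  expect_equal(t$is_paired[t$qname == "se"], FALSE)
})

test_that("barcodes separate otherwise identical templates", {
  sam <- sam_from_text(
    pe_pair_lines("c1a", extra_tags = "CB:Z:AAA"),
    pe_pair_lines("c2a", extra_tags = "CB:Z:TTT"),
    pe_pair_lines("c1b", extra_tags = "CB:Z:AAA")
  )
  off <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  expect_equal(marked_qnames(off), c("c1b", "c2a"))
  auto <- mark_duplicates(sam, barcode = "auto", bin_width = 1000, padding = 100)
  expect_equal(marked_qnames(auto), "c1b")
})

test_that("remove mode drops duplicate templates entirely", {
  sam <- sam_from_text(pe_pair_lines("t1"), pe_pair_lines("t2"))
  res <- mark_duplicates(sam, remove = TRUE, bin_width = 1000, padding = 100)
  expect_equal(unique(res$records$qname), "t1")
  expect_equal(nrow(res$records), 2L)
  # conservation without removal
  res2 <- mark_duplicates(sam, bin_width = 1000, padding = 100)
  expect_equal(nrow(res2$records), nrow(sam))
})

test_that("marking changes FLAG bit 0x400 and nothing else", {
  cfg <- sim_config(
    seed = 51, n_templates = 120, planted_dup_rate = 0.3,
    barcode_n = 3, tag_frac = 0.7
  )
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(cfg, ref)
  res <- mark_duplicates(sim$sam,
    reference = ref, barcode = "auto",
    bin_width = 1e5, padding = 1000
  )
  out <- res$records
  expect_identical(bitwAnd(out$flag, bitwNot(0x400L)), bitwAnd(sim$sam$flag, bitwNot(0x400L)))
  for (col in c("qname", "rname", "pos", "mapq", "cigar", "rnext", "pnext", "tlen", "seq", "qual", "tags")) {
    expect_identical(out[[col]], sim$sam[[col]])
  }
})

test_that("coordinate-sorted input and malformed groups are fatal", {
  sam <- sam_from_text(
    sam_line("a", 0L, pos = 10L),
    sam_line("b", 0L, pos = 20L),
    sam_line("a", 0L, pos = 30L)
  )
  expect_error(mark_duplicates(sam), "not name-grouped")
  dup1 <- sam_from_text(
    sam_line("a", 99L, pos = 10L, rnext = "=", pnext = 200L),
    sam_line("a", 99L, pos = 12L, rnext = "=", pnext = 200L)
  )
  expect_error(mark_duplicates(dup1), "more than one primary")
})
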