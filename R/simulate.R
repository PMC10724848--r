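#' Configuration for the synthetic WGBS alignment generator
#'
#' The generator emulates the structure of a bisulfite sequencing
#' library: unique genomic fragments drawn from either the top
#' (OT/CTOT) or bottom (OB/CTOB) strand, PCR duplicate copies planted as
#' byte-identical re-sequencings of a fragment, bisulfite conversion
#' (C->T on top-strand templates, G->A on bottom-strand templates,
#' relative to the reference), soft/hard clipping, aligner strand tags,
#' cell barcodes, secondary/supplementary records, and unmapped mates.
#' Generation is a pure function of the configuration: the same config
#' yields byte-identical output.
#'
#' @param seed RNG seed.
#' @param n_contigs,contig_length Reference shape (contigs of equal
#'   length, bp).
#' @param n_templates Number of unique fragments (planted duplicates are
#'   added on top of these).
#' @param planted_dup_rate Per-copy duplication rate: each fragment gets
#'   `k` extra copies with probability proportional to `rate^k`
#'   (truncated geometric, max 5). 0 plants no duplicates.
#' @param strand_mix Probability a fragment derives from the top strand.
#' @param conversion_rate Probability an unmethylated eligible base is
#'   bisulfite-converted. Real libraries achieve >= 0.98.
#' @param methylation_rate Probability an eligible site is methylated
#'   (and therefore never converted).
#' @param read_length Read length in bp.
#' @param paired_frac Fraction of fragments sequenced paired-end.
#' @param clip_prob,max_clip Per-read-end probability and maximum length
#'   of a 5' clip (soft, or hard with probability 0.3).
#' @param barcode_n Size of the cell-barcode pool (0 = no barcodes).
#' @param tag_frac Fraction of templates carrying an aligner strand tag
#'   (YD/XG/XB, drawn 60/25/15).
#' @param secondary_rate Per-template probability of one extra secondary
#'   or supplementary record.
#' @param both_unmapped_rate,one_unmapped_rate Per-paired-fragment
#'   probabilities of both or one mate being unmapped.
#' @param insert_min,insert_max Paired-end insert size range (bp).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 2L, contig_length = 50000L,
                       n_templates = 1000L, planted_dup_rate = 0.1,
                       strand_mix = 0.5, conversion_rate = 0.98,
                       methylation_rate = 0.75, read_length = 100L,
                       paired_frac = 0.8, clip_prob = 0.2, max_clip = 10L,
                       barcode_n = 0L, tag_frac = 1, secondary_rate = 0.05,
                       both_unmapped_rate = 0.02, one_unmapped_rate = 0.02,
                       insert_min = 150L, insert_max = 400L) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_templates = as.integer(n_templates),
    planted_dup_rate = planted_dup_rate, strand_mix = strand_mix,
    conversion_rate = conversion_rate, methylation_rate = methylation_rate,
    read_length = as.integer(read_length), paired_frac = paired_frac,
    clip_prob = clip_prob, max_clip = as.integer(max_clip),
    barcode_n = as.integer(barcode_n), tag_frac = tag_frac,
    secondary_rate = secondary_rate,
    both_unmapped_rate = both_unmapped_rate,
    one_unmapped_rate = one_unmapped_rate,
    insert_min = as.integer(insert_min), insert_max = as.integer(insert_max)
  )
  probs <- c(
    cfg$planted_dup_rate, cfg$strand_mix, cfg$conversion_rate,
    cfg$methylation_rate, cfg$paired_frac, cfg$clip_prob, cfg$tag_frac,
    cfg$secondary_rate, cfg$both_unmapped_rate, cfg$one_unmapped_rate
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all rate/probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$insert_min < cfg$read_length || cfg$insert_max < cfg$insert_min) {
    stop("insert range must satisfy read_length <= insert_min <= insert_max",
      call. = FALSE
    )
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome
#'
#' Uniform-random ACGT contigs named `chr1`, `chr2`, ...; deterministic
#' under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_reference <- function(cfg) {
  if (cfg$contig_length < cfg$read_length + cfg$max_clip) {
    stop("contig_length must be at least read_length + max_clip", call. = FALSE)
  }
  if (cfg$contig_length < cfg$insert_max) {
    stop("contig_length must be at least insert_max", call. = FALSE)
  }
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$contig_length, replace = TRUE),
      collapse = ""
    )
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(cfg$n_contigs))
  Biostrings::DNAStringSet(seqs)
}

#' Write a reference to FASTA and index it
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return `path`, invisibly (with a `.fai` index alongside).
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

# Apply bisulfite conversion to reference-orientation windows.
# Top-strand templates convert unmethylated C -> T; bottom-strand
# templates G -> A. Methylation state and conversion are drawn per site.
convert_windows <- function(wins, strand, conversion_rate, methylation_rate) {
  p <- (1 - methylation_rate) * conversion_rate
  if (p == 0) {
    return(wins)
  }
  from <- ifelse(strand == STRAND_TOP, "C", "G")
  to <- ifelse(strand == STRAND_TOP, "T", "A")
  sp <- strsplit(wins, "", fixed = TRUE)
  vapply(seq_along(sp), function(i) {
    ch <- sp[[i]]
    site <- which(ch == from[i])
    if (length(site)) {
      conv <- site[stats::runif(length(site)) < p]
      ch[conv] <- to[i]
    }
    paste(ch, collapse = "")
  }, character(1))
}

#' Simulate name-grouped WGBS alignments with planted duplicates
#'
#' Emits a name-grouped SAM tibble and a truth table. Each unique
#' fragment receives `1 + k` sequenced copies (`k` truncated-geometric
#' at `planted_dup_rate`); copies are byte-identical to the original
#' except for their QNAME (PCR copies are sequence- and clip-identical).
#' Distinct fragments are guaranteed distinct duplicate signatures
#' (rejection resampling), so the truth table's duplicate relation is
#' exactly recoverable. The first occurrence of a fragment in the
#' emitted stream is the truth nonduplicate.
#'
#' @param cfg A [sim_config()].
#' @param reference A [Biostrings::DNAStringSet] from
#'   [simulate_reference()] (or a named character vector).
#' @return A list with `sam` (a `sam_tbl`) and `truth` (tibble with
#'   `qname`, `fragment_id`, `strand`, `barcode`, `is_planted_dup`).
#' @export
simulate_alignments <- function(cfg, reference) {
  refs <- if (inherits(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else {
    reference
  }
  rl <- cfg$read_length
  n <- cfg$n_templates
  clen <- nchar(refs)
  set.seed(cfg$seed + 1L)

  # --- unique fragments ---------------------------------------------------
  ci <- sample.int(length(refs), n, replace = TRUE)
  paired <- stats::runif(n) < cfg$paired_frac
  strand <- ifelse(stats::runif(n) < cfg$strand_mix, STRAND_TOP, STRAND_BOTTOM)
  barcode <- if (cfg$barcode_n > 0L) {
    sample(sprintf("BC%02d", seq_len(cfg$barcode_n)), n, replace = TRUE)
  } else {
    rep(NA_character_, n)
  }
  fate <- rep("se", n)
  u <- stats::runif(n)
  fate[paired] <- "pe"
  fate[paired & u < cfg$both_unmapped_rate] <- "pe0"
  fate[paired & u >= cfg$both_unmapped_rate &
    u < cfg$both_unmapped_rate + cfg$one_unmapped_rate] <- "pe1"

  insert <- ifelse(paired,
    sample(seq(cfg$insert_min, cfg$insert_max), n, replace = TRUE), rl
  )
  start <- integer(n)
  r1fwd <- logical(n)
  resample <- seq_len(n)
  for (iter in 1:100) {
    m <- length(resample)
    start[resample] <- floor(stats::runif(m) * (clen[ci[resample]] - insert[resample] + 1)) + 1L
    r1fwd[resample] <- stats::runif(m) < 0.5
    end <- start + insert - 1L
    ekey <- sim_effective_key(fate, ci, start, end, r1fwd, strand, barcode)
    resample <- which(duplicated(ekey) & fate != "pe0")
    if (length(resample) == 0L) break
  }
  if (length(resample)) {
    stop("could not place ", length(resample), " fragments without ",
      "signature collisions; enlarge the reference or reduce n_templates",
      call. = FALSE
    )
  }
  end <- start + insert - 1L

  # 5' clips per read end (left read / right read)
  draw_clip <- function() {
    len <- ifelse(stats::runif(n) < cfg$clip_prob & cfg$max_clip > 0L,
      sample.int(cfg$max_clip, n, replace = TRUE), 0L
    )
    list(len = len, hard = stats::runif(n) < 0.3)
  }
  clL <- draw_clip()
  clR <- draw_clip()

  tagged <- stats::runif(n) < cfg$tag_frac
  tag_kind <- sample(c("YD", "XG", "XB"), n, replace = TRUE, prob = c(.6, .25, .15))
  has_sec <- stats::runif(n) < cfg$secondary_rate & fate != "pe0"
  sec_suppl <- stats::runif(n) < 0.5
  sec_pos <- floor(stats::runif(n) * (clen[ci] - rl + 1)) + 1L

  # converted read windows (reference orientation; copies reuse these)
  contig_name <- names(refs)[ci]
  win_l <- substr(refs[ci], start, start + rl - 1L)
  win_r <- substr(refs[ci], end - rl + 1L, end)
  win_l <- convert_windows(win_l, strand, cfg$conversion_rate, cfg$methylation_rate)
  win_r <- convert_windows(win_r, strand, cfg$conversion_rate, cfg$methylation_rate)

  strand_tag <- function(kind, strand) {
    ifelse(kind == "YD", paste0("YD:Z:", ifelse(strand == STRAND_TOP, "f", "r")),
      ifelse(kind == "XG", paste0("XG:Z:", ifelse(strand == STRAND_TOP, "CT", "GA")),
        paste0("XB:Z:", ifelse(strand == STRAND_TOP, "C", "G"))
      )
    )
  }
  tagstr <- rep(NA_character_, n)
  tagstr[tagged] <- strand_tag(tag_kind[tagged], strand[tagged])
  bcstr <- ifelse(is.na(barcode), NA_character_, paste0("CB:Z:", barcode))
  tags <- ifelse(is.na(tagstr), bcstr,
    ifelse(is.na(bcstr), tagstr, paste(tagstr, bcstr, sep = "\t"))
  )

  # --- assemble one record block per fragment -----------------------------
  clip_cigar <- function(clip, hard, lead) {
    code <- ifelse(hard, "H", "S")
    ifelse(clip == 0L, paste0(rl, "M"),
      ifelse(rep(lead, n),
        paste0(clip, code, rl - clip, "M"),
        paste0(rl - clip, "M", clip, code)
      )
    )
  }
  clip_seq <- function(win, clip, hard, lead) {
    ifelse(clip == 0L | !hard, win,
      ifelse(rep(lead, n), substr(win, clip + 1L, rl), substr(win, 1L, rl - clip))
    )
  }

  # left (forward) read: 5' clip is leading
  pos_l <- start + clL$len
  cigar_l <- clip_cigar(clL$len, clL$hard, TRUE)
  seq_l <- clip_seq(win_l, clL$len, clL$hard, TRUE)
  # right (reverse) read: 5' clip is trailing
  pos_r <- end - rl + 1L
  cigar_r <- clip_cigar(clR$len, clR$hard, FALSE)
  seq_r <- clip_seq(win_r, clR$len, clR$hard, FALSE)

  rec <- function(frag, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq) {
    tibble::tibble(
      frag = frag, flag = as.integer(flag), rname = rname,
      pos = as.integer(pos), mapq = mapq, cigar = cigar, rnext = rnext,
      pnext = as.character(pnext), tlen = as.character(tlen), seq = seq,
      qual = strrep("I", nchar(seq)), tags = tags[frag]
    )
  }

  blocks <- list()
  pe <- which(fate == "pe")
  if (length(pe)) {
    fl_l <- FLAG_PAIRED + FLAG_PROPER + FLAG_MREVERSE +
      ifelse(r1fwd[pe], FLAG_READ1, FLAG_READ2)
    fl_r <- FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE +
      ifelse(r1fwd[pe], FLAG_READ2, FLAG_READ1)
    blocks$pe_l <- rec(
      pe, fl_l, contig_name[pe], pos_l[pe], "60", cigar_l[pe],
      "=", pos_r[pe], insert[pe], seq_l[pe]
    )
    blocks$pe_r <- rec(
      pe, fl_r, contig_name[pe], pos_r[pe], "60", cigar_r[pe],
      "=", pos_l[pe], -insert[pe], seq_r[pe]
    )
  }
  pe1 <- which(fate == "pe1")
  if (length(pe1)) {
    fl_l <- FLAG_PAIRED + FLAG_MUNMAPPED +
      ifelse(r1fwd[pe1], FLAG_READ1, FLAG_READ2)
    fl_u <- FLAG_PAIRED + FLAG_UNMAPPED +
      ifelse(r1fwd[pe1], FLAG_READ2, FLAG_READ1)
    blocks$pe1_l <- rec(
      pe1, fl_l, contig_name[pe1], pos_l[pe1], "60", cigar_l[pe1],
      "=", pos_l[pe1], 0, seq_l[pe1]
    )
    blocks$pe1_u <- rec(
      pe1, fl_u, contig_name[pe1], pos_l[pe1], "0", "*",
      "=", pos_l[pe1], 0, win_r[pe1]
    )
  }
  pe0 <- which(fate == "pe0")
  if (length(pe0)) {
    fl1 <- FLAG_PAIRED + FLAG_UNMAPPED + FLAG_MUNMAPPED + FLAG_READ1
    fl2 <- FLAG_PAIRED + FLAG_UNMAPPED + FLAG_MUNMAPPED + FLAG_READ2
    blocks$pe0_1 <- rec(pe0, fl1, "*", 0, "0", "*", "*", 0, 0, win_l[pe0])
    blocks$pe0_2 <- rec(pe0, fl2, "*", 0, "0", "*", "*", 0, 0, win_r[pe0])
  }
  se <- which(fate == "se")
  if (length(se)) {
    sef <- se[r1fwd[se]]
    ser <- se[!r1fwd[se]]
    if (length(sef)) {
      blocks$se_f <- rec(
        sef, 0L, contig_name[sef], pos_l[sef], "60", cigar_l[sef],
        "*", 0, 0, seq_l[sef]
      )
    }
    if (length(ser)) {
      # reverse single-end read over the fragment window [start, end]
      blocks$se_r <- rec(
        ser, FLAG_REVERSE, contig_name[ser], start[ser], "60",
        clip_cigar(clR$len, clR$hard, FALSE)[ser], "*", 0, 0,
        clip_seq(win_l, clR$len, clR$hard, FALSE)[ser]
      )
    }
  }
  sec <- which(has_sec)
  if (length(sec)) {
    fl <- ifelse(sec_suppl[sec], FLAG_SUPPLEMENTARY, FLAG_SECONDARY) +
      ifelse(fate[sec] == "se" & !r1fwd[sec], FLAG_REVERSE, 0L) +
      ifelse(fate[sec] == "se", 0L,
        FLAG_PAIRED + ifelse(r1fwd[sec], FLAG_READ1, FLAG_READ2)
      )
    src_cigar <- ifelse(fate[sec] == "se" & !r1fwd[sec],
      clip_cigar(clR$len, clR$hard, FALSE)[sec], cigar_l[sec]
    )
    src_seq <- ifelse(fate[sec] == "se" & !r1fwd[sec],
      clip_seq(win_l, clR$len, clR$hard, FALSE)[sec], seq_l[sec]
    )
    blocks$sec <- rec(
      sec, fl, contig_name[sec], sec_pos[sec], "0", src_cigar,
      "*", 0, 0, src_seq
    )
  }
  frag_records <- dplyr::bind_rows(blocks)
  frag_records <- frag_records[order(frag_records$frag), ]

  # --- plant duplicate copies and emit in shuffled template order ---------
  extra <- pmin(stats::rgeom(n, prob = 1 - cfg$planted_dup_rate), 5L)
  extra[fate == "pe0"] <- 0L # a pass-through template carries no relation
  frag_of_template <- rep.int(seq_len(n), 1L + extra)
  emit <- sample(frag_of_template)
  rows_by_frag <- split(seq_len(nrow(frag_records)), frag_records$frag)
  rows <- unlist(rows_by_frag[emit], use.names = FALSE)
  n_per <- lengths(rows_by_frag)[emit]
  qn <- sprintf("t%06d", seq_along(emit))
  sam <- frag_records[rows, ]
  sam$qname <- rep(qn, n_per)
  sam <- dplyr::select(
    sam, "qname", "flag", "rname", "pos", "mapq", "cigar",
    "rnext", "pnext", "tlen", "seq", "qual", "tags"
  )
  header <- c(
    "@HD\tVN:1.6\tGO:query",
    paste0("@SQ\tSN:", names(refs), "\tLN:", clen)
  )
  truth <- tibble::tibble(
    qname = qn,
    fragment_id = sprintf("f%06d", emit),
    strand = strand[emit],
    barcode = ifelse(is.na(barcode[emit]), "*", barcode[emit]),
    is_planted_dup = duplicated(emit)
  )
  list(sam = new_sam_tbl(sam, header), truth = truth)
}

# Engine-visible identity of a fragment, used to keep distinct fragments
# from colliding by chance during generation.
sim_effective_key <- function(fate, ci, start, end, r1fwd, strand, barcode) {
  bc <- ifelse(is.na(barcode), "*", barcode)
  key <- character(length(fate))
  pe <- fate == "pe"
  key[pe] <- paste(
    "PE", ci[pe],
    ifelse(r1fwd[pe], start[pe], end[pe]), ifelse(r1fwd[pe], "F", "R"),
    ifelse(r1fwd[pe], end[pe], start[pe]), ifelse(r1fwd[pe], "R", "F"),
    strand[pe], bc[pe]
  )
  pe1 <- fate == "pe1"
  key[pe1] <- paste("PE1", ci[pe1], start[pe1], "F", strand[pe1], bc[pe1])
  se <- fate == "se"
  key[se] <- paste(
    "SE", ci[se], ifelse(r1fwd[se], start[se], end[se]),
    ifelse(r1fwd[se], "F", "R"), strand[se], bc[se]
  )
  pe0 <- fate == "pe0"
  key[pe0] <- paste("U", seq_along(fate)[pe0])
  key
}

#' Simulate co-located top/bottom strand fragment pairs
#'
#' The scenario a bisulfite-aware duplicate marker exists for: pairs of
#' paired-end templates occupying identical coordinates with identical
#' orientation, one derived from the top strand and one from the bottom.
#' These are distinct molecules — a bisulfite-aware run must mark
#' neither; a single-strand (WGS-mode) run collapses each pair and marks
#' exactly one.
#'
#' @param n_pairs Number of co-located pairs.
#' @param seed RNG seed.
#' @param contig_length,read_length,insert Geometry (bp).
#' @return A list with `reference` (DNAStringSet), `sam` (a `sam_tbl`;
#'   YD strand tags present), and `pairs` (tibble mapping qname to pair
#'   id and strand).
#' @export
simulate_strand_pairs <- function(n_pairs, seed = 1L, contig_length = NULL,
                                  read_length = 100L, insert = 300L) {
  contig_length <- contig_length %||% max(2L * n_pairs + insert + 10L, 1000L)
  cfg <- sim_config(
    seed = seed, n_contigs = 1L, contig_length = contig_length,
    read_length = read_length, insert_min = insert, insert_max = insert
  )
  reference <- simulate_reference(cfg)
  set.seed(seed + 2L)
  start <- sample.int(contig_length - insert, n_pairs)
  recs <- lapply(seq_len(n_pairs), function(i) {
    lapply(c(STRAND_TOP, STRAND_BOTTOM), function(st) {
      qn <- sprintf("p%05d_%s", i, tolower(st))
      yd <- paste0("YD:Z:", if (st == STRAND_TOP) "f" else "r")
      pos1 <- start[i]
      pos2 <- start[i] + insert - read_length
      tibble::tibble(
        qname = qn,
        flag = c(
          FLAG_PAIRED + FLAG_PROPER + FLAG_MREVERSE + FLAG_READ1,
          FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE + FLAG_READ2
        ),
        rname = "chr1", pos = c(pos1, pos2), mapq = "60",
        cigar = paste0(read_length, "M"), rnext = "=",
        pnext = as.character(c(pos2, pos1)),
        tlen = as.character(c(insert, -insert)),
        seq = strrep("A", read_length), qual = strrep("I", read_length),
        tags = yd
      )
    })
  })
  sam <- dplyr::bind_rows(unlist(recs, recursive = FALSE))
  header <- c(
    "@HD\tVN:1.6\tGO:query",
    paste0("@SQ\tSN:chr1\tLN:", contig_length)
  )
  pairs <- tibble::tibble(
    qname = sam$qname[!duplicated(sam$qname)],
    pair = rep(seq_len(n_pairs), each = 2L),
    strand = rep(c(STRAND_TOP, STRAND_BOTTOM), n_pairs)
  )
  list(reference = reference, sam = new_sam_tbl(sam, header), pairs = pairs)
}

#' Brute-force duplicate-marking oracle
#'
#' An independent all-pairs re-statement of the duplicate rule, used to
#' validate the streaming engine: every template's signature fields are
#' recomputed here from the raw SAM fields (separate clip arithmetic and
#' supercontig layout code, no shared signature store or hashing), and
#' within each equivalence class of (signature fields, strand class)
#' every template except the first in input order is marked. Quadratic;
#' small inputs only.
#'
#' @param sam A `sam_tbl`.
#' @param reference Optional reference for strand fallback.
#' @param mode `"bisulfite"` or `"wgs"`.
#' @param barcode Barcode mode (`"off"` or `"auto"`).
#' @param bin_width,padding Supercontig parameters (must match the
#'   engine run being checked).
#' @return Character vector of marked template QNAMEs.
#' @export
oracle_mark <- function(sam, reference = NULL, mode = "bisulfite",
                        barcode = "off", bin_width = 2^26, padding = 10000) {
  contigs <- sam_contigs(sam_header(sam))
  # independent supercontig layout: left pad, contig, right pad, per contig
  slot <- contigs$length + padding
  slot_start <- stats::setNames(
    cumsum(c(0, slot[-length(slot)])) + floor(padding / 2),
    contigs$name
  )
  strand_tbl <- infer_strand(sam, reference, mode)
  strand_by_qn <- stats::setNames(strand_tbl$strand, strand_tbl$qname)

  qn_runs <- rle(sam$qname)$values
  feats <- vector("list", length(qn_runs))
  for (g in seq_along(qn_runs)) {
    grp <- sam[sam$qname == qn_runs[g], ]
    prim <- grp[bitwAnd(grp$flag, 0x900L) == 0L, ]
    mapped <- bitwAnd(prim$flag, 0x4L) == 0L
    if (!any(mapped)) next # pass-through, never marked
    five <- function(row) {
      clips <- function(cg, lead) {
        pat <- if (lead) "^(\\d+[SH])+" else "(\\d+[SH])+$"
        m <- regmatches(cg, regexpr(pat, cg))
        if (length(m) == 0L) {
          return(0)
        }
        sum(as.numeric(regmatches(m, gregexpr("\\d+", m))[[1L]]))
      }
      reflen <- sum(as.numeric(unlist(regmatches(
        row$cigar, gregexpr("\\d+(?=[MDN=X])", row$cigar, perl = TRUE)
      ))))
      if (bitwAnd(row$flag, 0x10L) != 0L) {
        (row$pos - 1) + reflen + clips(row$cigar, FALSE) - 1
      } else {
        (row$pos - 1) - clips(row$cigar, TRUE)
      }
    }
    scoord <- function(row) slot_start[[row$rname]] + five(row)
    is_paired <- bitwAnd(prim$flag[1L], 0x1L) != 0L
    i1 <- if (is_paired) which(bitwAnd(prim$flag, 0x40L) != 0L) else 1L
    i2 <- if (is_paired) which(bitwAnd(prim$flag, 0x80L) != 0L) else integer()
    m1 <- length(i1) == 1L && mapped[i1]
    m2 <- length(i2) == 1L && mapped[i2]
    a <- if (m1) prim[i1, ] else prim[i2, ]
    b <- if (m1 && m2) prim[i2, ] else NULL
    s1 <- scoord(a)
    s2 <- if (!is.null(b)) scoord(b) else -1
    bc <- "*"
    if (identical(barcode, "auto")) {
      tg <- paste(stats::na.omit(grp$tags), collapse = "\t")
      cb <- regmatches(tg, regexpr("CB:Z:[^\t]*", tg))
      cr <- regmatches(tg, regexpr("CR:Z:[^\t]*", tg))
      bc <- if (length(cb)) {
        sub("^CB:Z:", "", cb)
      } else if (length(cr)) {
        sub("^CR:Z:", "", cr)
      } else {
        parts <- strsplit(qn_runs[g], ":", fixed = TRUE)[[1L]]
        parts[length(parts)]
      }
    }
    feats[[g]] <- data.frame(
      qname = qn_runs[g],
      s1 = s1, s2 = s2,
      r1_left = is.null(b) || s1 <= s2,
      o1 = bitwAnd(a$flag, 0x10L) != 0L,
      o2 = !is.null(b) && bitwAnd(b$flag, 0x10L) != 0L,
      paired = is_paired,
      barcode = bc,
      strand = strand_by_qn[[qn_runs[g]]]
    )
  }
  ft <- dplyr::bind_rows(feats)
  if (is.null(ft) || nrow(ft) == 0L) {
    return(character())
  }
  marked <- logical(nrow(ft))
  for (i in seq_len(nrow(ft))[-1L]) {
    j <- seq_len(i - 1L)
    same <- ft$s1[j] == ft$s1[i] & ft$s2[j] == ft$s2[i] &
      ft$r1_left[j] == ft$r1_left[i] &
      ft$o1[j] == ft$o1[i] & ft$o2[j] == ft$o2[i] &
      ft$paired[j] == ft$paired[i] &
      ft$barcode[j] == ft$barcode[i] &
      ft$strand[j] == ft$strand[i]
    marked[i] <- any(same)
  }
  ft$qname[marked]
}
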