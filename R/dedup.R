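#' Mark PCR duplicates in a name-grouped alignment stream
#'
#' The core engine. For each template (all records sharing a QNAME) it
#' determines the bisulfite strand class, builds the clip-corrected read
#' signature from the primary records only, and looks the pair
#' (signature, strand class) up in a per-class store: the first
#' occurrence is the nonduplicate, every later occurrence is a
#' duplicate. The verdict is applied to the whole template — primary,
#' secondary, and supplementary records alike — by setting or clearing
#' FLAG bit 0x400. Pre-existing duplicate flags from upstream tools are
#' recomputed, which makes runs idempotent and aligner-agnostic.
#' Templates with no mapped primary record (both-unmapped pairs,
#' unmapped single-end reads) pass through untouched.
#'
#' In `wgs` mode all templates are assigned one strand class, so
#' co-located top- and bottom-strand fragments — distinct molecules in a
#' bisulfite library — collapse into one duplicate class; `bisulfite`
#' mode keeps them apart.
#'
#' @param sam A `sam_tbl` from [read_sam()] (name-grouped order).
#' @param reference Optional reference for conversion-count strand
#'   fallback: a FASTA path, `ref_genome`, or `DNAStringSet`.
#' @param mode `"bisulfite"` (default) or `"wgs"`.
#' @param barcode Barcode mode, see [extract_barcode()]. Default `"off"`.
#' @param bin_width,padding Supercontig binning parameters, see
#'   [build_bin_map()].
#' @param remove If `TRUE`, duplicate templates are dropped from the
#'   output instead of flagged.
#' @param tag_priority Strand tags to try, in order.
#' @return An object of class `dup_marking`: a list with `records` (the
#'   output `sam_tbl`), `templates` (per-template decisions, see
#'   [tidy.dup_marking()]), and `stats` (named list of counters, see
#'   [glance.dup_marking()]).
#' @export
#' @examples
#' sam <- read_sam(system.file("extdata", "toy.sam", package = "bsmarkdup"))
#' res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
#' glance(res)
mark_duplicates <- function(sam, reference = NULL,
                            mode = c("bisulfite", "wgs"),
                            barcode = "off",
                            bin_width = 2^26, padding = 10000,
                            remove = FALSE,
                            tag_priority = c("YD", "XG", "XB")) {
  mode <- match.arg(mode)
  header <- sam_header(sam)
  tid <- check_name_grouped(sam$qname)
  n_t <- if (nrow(sam)) max(tid) else 0L
  qname_t <- sam$qname[!duplicated(tid)]

  flag <- sam$flag
  primary <- !has_flag(flag, FLAG_SECONDARY) & !has_flag(flag, FLAG_SUPPLEMENTARY)
  mapped <- !has_flag(flag, FLAG_UNMAPPED)
  paired <- has_flag(flag, FLAG_PAIRED)
  isr1 <- primary & (!paired | has_flag(flag, FLAG_READ1))
  isr2 <- primary & paired & has_flag(flag, FLAG_READ2)
  if (anyDuplicated(tid[isr1]) || anyDuplicated(tid[isr2])) {
    bad <- c(tid[isr1][duplicated(tid[isr1])], tid[isr2][duplicated(tid[isr2])])[1L]
    stop("template '", qname_t[bad], "' has more than one primary read-1 ",
      "or read-2 record",
      call. = FALSE
    )
  }

  r1 <- r2 <- rep(NA_integer_, n_t)
  r1[tid[isr1]] <- which(isr1)
  r2[tid[isr2]] <- which(isr2)
  m1 <- !is.na(r1) & mapped[replace(r1, is.na(r1), 1L)]
  m2 <- !is.na(r2) & mapped[replace(r2, is.na(r2), 1L)]
  passthrough <- !m1 & !m2

  contigs <- sam_contigs(header)
  any_processed <- any(!passthrough)
  map <- NULL
  if (any_processed) {
    if (nrow(contigs) == 0L) {
      stop("mapped records present but header has no @SQ lines", call. = FALSE)
    }
    map <- build_bin_map(contigs, bin_width = bin_width, padding = padding)
  }

  # --- per-template fields ------------------------------------------------
  # The read-1 slot ("anchor") is the primary read 1 when it is mapped,
  # otherwise the mapped mate (one-mate-unmapped templates are keyed like
  # single-end reads on the mapped mate, keeping is_paired in the key).
  anchor <- ifelse(m1, r1, r2)
  mate <- ifelse(m1 & m2, r2, NA_integer_)
  proc <- which(!passthrough)

  dup_t <- rep(FALSE, n_t)
  strand_t <- rep(NA_character_, n_t)
  strand_source <- rep(NA_character_, n_t)
  templates <- NULL

  if (length(proc)) {
    # 5' unclipped positions of every mapped primary we will key on
    need <- unique(c(anchor[proc], mate[proc][!is.na(mate[proc])]))
    five <- rep(NA_real_, nrow(sam))
    five[need] <- unclipped_5prime(
      sam$pos[need] - 1, sam$cigar[need], has_flag(flag[need], FLAG_REVERSE)
    )

    tags_at <- function(i) ifelse(is.na(i), NA_character_, sam$tags[replace(i, is.na(i), 1L)])
    st <- infer_strand_internal(
      sam, tid, r1, r2, m1, m2, proc, mode, reference, tag_priority
    )
    strand_t[proc] <- st$strand
    strand_source[proc] <- st$source

    tmpl <- tibble::tibble(
      qname = qname_t[proc],
      anchor_contig = sam$rname[anchor[proc]],
      anchor_5p = five[anchor[proc]],
      anchor_reverse = has_flag(flag[anchor[proc]], FLAG_REVERSE),
      mate_contig = ifelse(is.na(mate[proc]), NA_character_,
        sam$rname[replace(mate[proc], is.na(mate[proc]), 1L)]
      ),
      mate_5p = ifelse(is.na(mate[proc]), NA_real_,
        five[replace(mate[proc], is.na(mate[proc]), 1L)]
      ),
      mate_reverse = ifelse(is.na(mate[proc]), NA,
        has_flag(flag[replace(mate[proc], is.na(mate[proc]), 1L)], FLAG_REVERSE)
      ),
      is_paired = paired[anchor[proc]],
      barcode = extract_barcode(
        tags_at(r1[proc]), tags_at(r2[proc]), qname_t[proc], barcode
      )
    )
    tmpl <- build_signature(tmpl, map)
    tmpl$strand <- strand_t[proc]
    # first occurrence per (strand class, signature) wins
    tmpl$duplicate <- duplicated(paste(tmpl$strand, tmpl$sig_key, sep = "\r"))
    dup_t[proc] <- tmpl$duplicate
    templates <- tmpl
  }

  # --- apply the verdict --------------------------------------------------
  out_flag <- flag
  touched <- !passthrough[tid]
  out_flag[touched] <- set_flag(flag[touched], FLAG_DUP, dup_t[tid[touched]])
  out <- sam
  out$flag <- out_flag
  if (remove) out <- out[!dup_t[tid], ]
  out <- new_sam_tbl(out, header)

  stats <- list(
    templates_total = n_t,
    templates_marked_dup = sum(dup_t),
    reads_total = nrow(sam),
    reads_marked_dup = sum(dup_t[tid]),
    pairs_both_unmapped_passed = sum(passthrough),
    strand_unknown_fallbacks = sum(strand_source == "default", na.rm = TRUE),
    top_seen = sum(strand_t == STRAND_TOP & !dup_t, na.rm = TRUE),
    bottom_seen = sum(strand_t == STRAND_BOTTOM & !dup_t, na.rm = TRUE)
  )

  structure(
    list(
      records = out,
      templates = templates %||% tibble::tibble(),
      passthrough = qname_t[passthrough],
      stats = stats,
      mode = mode,
      params = list(
        barcode = barcode, bin_width = bin_width, padding = padding,
        remove = remove, tag_priority = tag_priority
      )
    ),
    class = "dup_marking"
  )
}

# Strand determination over the processed templates only; mirrors
# infer_strand() but reuses the index vectors the engine already built.
infer_strand_internal <- function(sam, tid, r1, r2, m1, m2, proc, mode,
                                  reference, tag_priority) {
  if (mode == "wgs") {
    return(list(
      strand = rep(STRAND_TOP, length(proc)),
      source = rep("wgs", length(proc))
    ))
  }
  reference <- as_ref_genome(reference)
  tags_at <- function(i) ifelse(is.na(i), NA_character_, sam$tags[replace(i, is.na(i), 1L)])
  strand <- strand_from_tags(tags_at(r1[proc]), tags_at(r2[proc]), tag_priority)
  source <- ifelse(strand == STRAND_UNKNOWN, "default", "tag")
  unknown <- which(strand == STRAND_UNKNOWN)
  if (length(unknown) && !is.null(reference)) {
    for (k in unknown) {
      t <- proc[k]
      idx <- c(if (m1[t]) r1[t], if (m2[t]) r2[t])
      if (length(idx) == 0L) next
      strand[k] <- strand_from_conversions(sam[idx, ], reference)
      source[k] <- "conversion"
    }
  }
  strand[strand == STRAND_UNKNOWN] <- STRAND_TOP
  list(strand = strand, source = source)
}

#' @export
print.dup_marking <- function(x, ...) {
  s <- x$stats
  cat("<dup_marking> mode=", x$mode, "\n",
    "  templates: ", s$templates_total, " (", s$templates_marked_dup,
    " marked duplicate, ", s$pairs_both_unmapped_passed, " passed unmapped)\n",
    "  records:   ", s$reads_total, " (", s$reads_marked_dup, " marked)\n",
    sep = ""
  )
  invisible(x)
}

#' Per-template decisions of a duplicate-marking run
#'
#' @param x A `dup_marking` object.
#' @param ... Unused.
#' @return A tibble with one row per processed template: signature
#'   fields, strand class, and the `duplicate` verdict.
#' @method tidy dup_marking
#' @export
tidy.dup_marking <- function(x, ...) {
  if (nrow(x$templates) == 0L) {
    return(x$templates)
  }
  dplyr::select(
    x$templates, "qname", "strand", "bin1", "pos1", "bin2", "pos2",
    "r1_left", "orientation", "is_paired", "barcode", "duplicate"
  )
}

#' One-row summary of a duplicate-marking run
#'
#' @param x A `dup_marking` object.
#' @param ... Unused.
#' @return A one-row tibble of run counters, including the duplicate
#'   rate among processed templates.
#' @method glance dup_marking
#' @export
glance.dup_marking <- function(x, ...) {
  s <- x$stats
  processed <- s$templates_total - s$pairs_both_unmapped_passed
  tibble::tibble(
    templates_total = s$templates_total,
    templates_marked_dup = s$templates_marked_dup,
    duplicate_rate = if (processed > 0) s$templates_marked_dup / processed else NA_real_,
    reads_total = s$reads_total,
    reads_marked_dup = s$reads_marked_dup,
    pairs_both_unmapped_passed = s$pairs_both_unmapped_passed,
    strand_unknown_fallbacks = s$strand_unknown_fallbacks,
    top_seen = s$top_seen,
    bottom_seen = s$bottom_seen
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the per-strand duplicate composition of a run
#'
#' @param object A `dup_marking` object.
#' @param ... Unused.
#' @return A ggplot: template counts by strand class, filled by
#'   duplicate status.
#' @method autoplot dup_marking
#' @export
autoplot.dup_marking <- function(object, ...) {
  t <- object$templates
  if (nrow(t) == 0L) {
    stop("no processed templates to plot", call. = FALSE)
  }
  t$status <- ifelse(t$duplicate, "duplicate", "unique")
  ggplot2::ggplot(t, ggplot2::aes(x = .data$strand, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "bisulfite strand class", y = "templates",
      fill = NULL, title = "Duplicate marking by strand class"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Write run statistics as key: value lines
#'
#' @param x A `dup_marking` object (or its `stats` list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dup_stats <- function(x, path) {
  s <- if (inherits(x, "dup_marking")) x$stats else x
  writeLines(paste0(names(s), ": ", unlist(s)), path)
  invisible(path)
}
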