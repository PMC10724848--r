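# Sentinel values used in the read-2 slot of single-end signatures and
# for the barcode when barcoding is off. bin -1 cannot collide with any
# real bin.
SIG_SENTINEL_BIN <- -1
SIG_SENTINEL_POS <- -1
SIG_SENTINEL_BARCODE <- "*"

#' Unclipped 5' position of a mapped record
#'
#' Restores the read's biological start by undoing soft/hard clipping at
#' the 5' end: forward-strand reads start at `POS - leading clip`;
#' reverse-strand reads start at the rightmost aligned base plus the
#' trailing clip (0-based inclusive). The result may overhang the contig
#' — the bin map's per-contig padding absorbs this.
#'
#' @param pos0 0-based leftmost mapped position(s).
#' @param cigar CIGAR string(s).
#' @param reverse Logical: is the reverse-strand FLAG (0x10) set?
#' @return Numeric 0-based 5' positions (possibly negative).
#' @export
#' @examples
#' unclipped_5prime(999, "5S95M", FALSE) # 994
#' unclipped_5prime(2000, "90M10S", TRUE) # 2099
unclipped_5prime <- function(pos0, cigar, reverse) {
  cs <- cigar_stats(cigar)
  ifelse(reverse,
    pos0 + cs$ref_len + cs$trail_clip - 1,
    pos0 - cs$lead_clip
  )
}

#' Extract the cell barcode of a template
#'
#' @param tags1,tags2 `tags` strings of the primary records (`NA` when
#'   absent).
#' @param qname Template names (used by the read-name modes).
#' @param mode One of:
#'   * `"off"` — a fixed sentinel for all templates (single-sample data);
#'   * `"auto"` — first available of the `CB` tag, the `CR` tag, then the
#'     last `":"`-separated field of the read name;
#'   * `"tag:XX"` — a specific two-character tag;
#'   * `"name:DELIM,IDX"` — split the read name on `DELIM` and take field
#'     `IDX` (an integer or `"last"`).
#' @return Character vector of barcodes.
#' @export
extract_barcode <- function(tags1, tags2 = NA_character_, qname = NULL,
                            mode = "off") {
  n <- max(length(tags1), length(tags2), length(qname))
  if (identical(mode, "off")) {
    return(rep(SIG_SENTINEL_BARCODE, n))
  }
  tags1 <- rep_len(tags1, n)
  tags2 <- rep_len(tags2, n)
  tag_bc <- function(tag) {
    dplyr::coalesce(sam_tag(tags1, tag), sam_tag(tags2, tag))
  }
  name_bc <- function(delim, idx) {
    parts <- strsplit(qname, delim, fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) < 2L) {
        return(NA_character_)
      }
      i <- if (identical(idx, "last")) length(p) else as.integer(idx)
      if (is.na(i) || i < 1L || i > length(p)) NA_character_ else p[i]
    }, character(1))
  }
  bc <- if (identical(mode, "auto")) {
    dplyr::coalesce(tag_bc("CB"), tag_bc("CR"), name_bc(":", "last"))
  } else if (startsWith(mode, "tag:")) {
    tag_bc(substr(mode, 5L, 6L))
  } else if (startsWith(mode, "name:")) {
    spec <- strsplit(substr(mode, 6L, nchar(mode)), ",", fixed = TRUE)[[1L]]
    if (length(spec) != 2L) {
      stop("barcode mode must be 'name:DELIM,IDX', got '", mode, "'", call. = FALSE)
    }
    name_bc(spec[1L], spec[2L])
  } else {
    stop("unknown barcode mode: '", mode, "'", call. = FALSE)
  }
  if (anyNA(bc)) {
    stop(
      "barcode mode '", mode, "' was requested but no barcode was found ",
      "for template '", qname[which(is.na(bc))[1L]] %||% "?",
      "'; check CB/CR tags or the read-name layout",
      call. = FALSE
    )
  }
  bc
}

#' Build duplicate-detection signatures for templates
#'
#' The signature of a template is the tuple that two PCR copies of one
#' molecule must share: the supercontig bin and within-bin position of
#' the unclipped 5' ends of read 1 and read 2, whether read 1 lies to
#' the left of read 2, the (read1, read2) orientation, pairedness, and
#' the barcode. Single-end templates (and paired templates with one
#' unmapped mate, which are keyed on the mapped mate but keep
#' `is_paired = TRUE` so they never collide with true single-end reads)
#' carry fixed sentinels in the read-2 slot and orientation `F` there.
#'
#' @param templates A data frame with one row per template carrying
#'   columns `anchor_contig`, `anchor_5p`, `anchor_reverse` (the read-1
#'   slot), optionally `mate_contig`, `mate_5p`, `mate_reverse` (`NA`
#'   when absent), `is_paired`, and `barcode`.
#' @param map A `genome_bin_map`.
#' @return The input tibble with signature columns `bin1`, `pos1`,
#'   `bin2`, `pos2`, `r1_left`, `orientation`, and a string `sig_key`
#'   whose equality is equality of all signature fields.
#' @export
build_signature <- function(templates, map) {
  t <- tibble::as_tibble(templates)
  s1 <- to_supercontig(map, t$anchor_contig, t$anchor_5p)
  b1 <- bin_of(map, s1)
  has_mate <- !is.na(t$mate_contig)
  bin2 <- rep(SIG_SENTINEL_BIN, nrow(t))
  pos2 <- rep(SIG_SENTINEL_POS, nrow(t))
  r1_left <- rep(TRUE, nrow(t))
  orient2 <- rep("F", nrow(t))
  if (any(has_mate)) {
    s2 <- to_supercontig(map, t$mate_contig[has_mate], t$mate_5p[has_mate])
    b2 <- bin_of(map, s2)
    bin2[has_mate] <- b2$bin
    pos2[has_mate] <- b2$offset
    r1_left[has_mate] <- s1[has_mate] <= s2
    orient2[has_mate] <- ifelse(t$mate_reverse[has_mate], "R", "F")
  }
  t$bin1 <- b1$bin
  t$pos1 <- b1$offset
  t$bin2 <- bin2
  t$pos2 <- pos2
  t$r1_left <- r1_left
  t$orientation <- paste0(ifelse(t$anchor_reverse, "R", "F"), orient2)
  t$sig_key <- paste(
    t$bin1, t$pos1, t$bin2, t$pos2, t$r1_left, t$orientation,
    t$is_paired, t$barcode,
    sep = "\r"
  )
  t
}
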