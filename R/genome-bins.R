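#' Build the supercontig bin map from reference contigs
#'
#' All contigs are laid end-to-end, in header `@SQ` order, into one
#' "supercontig" coordinate line. Each contig is placed inside a padded
#' slot — `floor(padding/2)` bp reserved before it and the remainder after
#' — so that clip-corrected read positions that overhang a contig edge
#' still map to a unique, non-negative supercontig coordinate. The
#' supercontig is then cut into fixed-width bins; a read position is
#' encoded as (bin number, offset within bin). The map itself is O(number
#' of contigs) in memory, independent of genome length.
#'
#' @param contigs A data frame with columns `name` and `length` (bp), in
#'   header order, e.g. from [sam_contigs()].
#' @param bin_width Bin width in bp (default `2^26`). Must exceed
#'   `padding` so an overhanging position cannot underflow ambiguously
#'   into the previous contig's last bin.
#' @param padding Padding bp reserved per contig for clipping overhang
#'   (default 10000).
#' @return An object of class `genome_bin_map`.
#' @export
#' @examples
#' m <- build_bin_map(data.frame(name = c("c1", "c2"), length = c(100, 200)),
#'   bin_width = 150, padding = 10
#' )
#' to_supercontig(m, "c2", 0) # 115
build_bin_map <- function(contigs, bin_width = 2^26, padding = 10000) {
  stopifnot(is.data.frame(contigs), all(c("name", "length") %in% names(contigs)))
  if (nrow(contigs) == 0L) stop("no contigs in header", call. = FALSE)
  if (anyDuplicated(contigs$name)) {
    stop("duplicate contig name in header: ",
      contigs$name[duplicated(contigs$name)][1L],
      call. = FALSE
    )
  }
  len <- as.numeric(contigs$length)
  if (any(is.na(len)) || any(len <= 0)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  if (padding < 0) stop("padding must be non-negative", call. = FALSE)
  if (bin_width <= padding) {
    stop("bin_width (", bin_width, ") must exceed padding (", padding, ")",
      call. = FALSE
    )
  }
  slot <- len + padding
  offset <- cumsum(c(0, slot[-length(slot)]))
  total <- sum(slot)
  structure(
    list(
      contig = as.character(contigs$name),
      offset = offset,
      length = len,
      padding = padding,
      pad_before = floor(padding / 2),
      bin_width = bin_width,
      total_length = total,
      n_bins = ceiling(total / bin_width)
    ),
    class = "genome_bin_map"
  )
}

#' @export
print.genome_bin_map <- function(x, ...) {
  cat(
    "<genome_bin_map> ", length(x$contig), " contigs, ",
    format(x$total_length, big.mark = ","), " bp supercontig (padding ",
    x$padding, "/contig), ", x$n_bins, " bins of ", x$bin_width, " bp\n",
    sep = ""
  )
  invisible(x)
}

#' Map a (contig, position) to the supercontig coordinate
#'
#' @param map A `genome_bin_map`.
#' @param contig Character vector of contig names (must exist in the map).
#' @param pos 0-based positions; may be negative (clip overhang before the
#'   contig start) or beyond the contig length (trailing overhang), within
#'   the padded slot.
#' @return Numeric supercontig coordinates in `[0, total_length)`.
#' @export
to_supercontig <- function(map, contig, pos) {
  i <- match(contig, map$contig)
  if (anyNA(i)) {
    stop(
      "contig not present in header @SQ lines: ",
      contig[is.na(i)][1L], " (header/alignment mismatch)",
      call. = FALSE
    )
  }
  pad_after <- map$padding - map$pad_before
  bad <- pos < -map$pad_before | pos >= map$length[i] + pad_after
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(
      "position ", pos[k], " on ", contig[k],
      " falls outside the padded contig slot (padding ", map$padding,
      " bp); increase --padding if clips this large are expected",
      call. = FALSE
    )
  }
  map$offset[i] + map$pad_before + pos
}

#' Decompose a supercontig coordinate into (bin, within-bin offset)
#'
#' @param map A `genome_bin_map`.
#' @param super_pos Numeric supercontig coordinates in `[0, total_length)`.
#' @return A tibble with integer-valued `bin` and `offset` columns.
#' @export
bin_of <- function(map, super_pos) {
  if (any(super_pos < 0 | super_pos >= map$total_length)) {
    stop("supercontig position out of range [0, ", map$total_length, ")",
      call. = FALSE
    )
  }
  tibble::tibble(
    bin = super_pos %/% map$bin_width,
    offset = super_pos %% map$bin_width
  )
}
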