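# SAM FLAG bits (SAM spec v1)
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MREVERSE <- 0x20L
FLAG_READ1 <- 0x40L
FLAG_READ2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Test a SAM FLAG bit
#'
#' @param flag Integer vector of SAM FLAG values.
#' @param bit A single FLAG bit, e.g. `0x400L` for the duplicate flag.
#' @return Logical vector.
#' @keywords internal
has_flag <- function(flag, bit) {
  bitwAnd(flag, bit) != 0L
}

set_flag <- function(flag, bit, on) {
  cleared <- bitwAnd(flag, bitwNot(bit))
  ifelse(on, bitwOr(cleared, bit), cleared)
}

#' Parse CIGAR strings into per-record summaries
#'
#' Computes, for each CIGAR string, the total leading clip (soft + hard
#' before the first aligned op), the trailing clip, and the number of
#' reference bases consumed (M/=/X/D/N). Results are computed once per
#' distinct CIGAR and mapped back, since duplicate-heavy inputs repeat
#' CIGARs.
#'
#' @param cigars Character vector of CIGAR strings ("*" allowed).
#' @return A data frame with columns `cigar`, `lead_clip`, `trail_clip`,
#'   `ref_len`, aligned with the input.
#' @keywords internal
cigar_stats <- function(cigars) {
  ucig <- unique(cigars)
  stats <- vapply(ucig, function(cg) {
    if (is.na(cg) || cg == "*") {
      return(c(0, 0, 0))
    }
    ops <- cigar_ops(cg)
    op <- ops$op
    len <- ops$len
    clip <- op %in% c("S", "H")
    nonclip <- which(!clip)
    if (length(nonclip) == 0L) {
      return(c(sum(len), 0, 0))
    }
    lead <- if (nonclip[1L] > 1L) sum(len[seq_len(nonclip[1L] - 1L)]) else 0
    last <- nonclip[length(nonclip)]
    trail <- if (last < length(op)) sum(len[(last + 1L):length(op)]) else 0
    ref_len <- sum(len[op %in% c("M", "=", "X", "D", "N")])
    c(lead, trail, ref_len)
  }, numeric(3))
  i <- match(cigars, ucig)
  data.frame(
    cigar = cigars,
    lead_clip = stats[1L, i],
    trail_clip = stats[2L, i],
    ref_len = stats[3L, i]
  )
}

# Split one CIGAR into op lengths and op codes.
cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) stop("malformed CIGAR: ", cigar, call. = FALSE)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  list(
    len = as.numeric(sub("[MIDNSHP=X]$", "", toks)),
    op = sub("^\\d+", "", toks)
  )
}

#' Extract a SAM auxiliary tag value
#'
#' @param tags Character vector of tab-joined auxiliary tag fields (the
#'   `tags` column of a SAM tibble); `NA` means no tags.
#' @param tag Two-character tag name, e.g. `"CB"`.
#' @return Character vector of values (`NA` where absent).
#' @keywords internal
sam_tag <- function(tags, tag) {
  pat <- paste0("(?:^|\t)", tag, ":[AifZHB]:([^\t]*)")
  m <- regexpr(pat, tags, perl = TRUE)
  out <- rep(NA_character_, length(tags))
  hit <- !is.na(tags) & m != -1L
  if (any(hit)) {
    st <- attr(m, "capture.start")[hit, 1L]
    len <- attr(m, "capture.length")[hit, 1L]
    out[hit] <- substr(tags[hit], st, st + len - 1L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
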