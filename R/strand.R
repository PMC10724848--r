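# Bisulfite strand classes. OT and CTOT reads both show C->T mismatches
# against the reference once SAM stores SEQ in reference orientation, so
# only two classes matter for duplicate detection: TOP (OT/CTOT) and
# BOTTOM (OB/CTOB). UNKNOWN is the fallback signal, not an error.
STRAND_TOP <- "TOP"
STRAND_BOTTOM <- "BOTTOM"
STRAND_UNKNOWN <- "UNKNOWN"

#' Open an indexed reference genome
#'
#' Wraps a FASTA file behind a small accessor used for conversion-count
#' strand inference. The `.fai` index is created with
#' [Rsamtools::indexFa()] if missing; contig sequences are fetched lazily
#' and cached in memory (uppercased).
#'
#' @param path Path to a FASTA file, or a [Biostrings::DNAStringSet] for
#'   an in-memory reference.
#' @return An object of class `ref_genome` with a `$fetch(contig)` method
#'   returning the contig sequence as a single uppercase string.
#' @export
open_reference <- function(path) {
  cache <- new.env(parent = emptyenv())
  if (inherits(path, "DNAStringSet")) {
    seqs <- as.character(path)
    fetch <- function(contig) {
      if (!contig %in% names(seqs)) {
        stop("contig '", contig, "' not present in reference", call. = FALSE)
      }
      toupper(seqs[[contig]])
    }
    return(structure(list(fetch = fetch, source = "<in-memory>"), class = "ref_genome"))
  }
  if (!file.exists(path)) stop("reference FASTA not found: ", path, call. = FALSE)
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  fa <- Rsamtools::FaFile(path)
  idx <- Rsamtools::scanFaIndex(fa)
  fetch <- function(contig) {
    if (!is.null(cache[[contig]])) {
      return(cache[[contig]])
    }
    hit <- which(as.character(GenomicRanges::seqnames(idx)) == contig)
    if (length(hit) == 0L) {
      stop("contig '", contig, "' not present in reference FASTA", call. = FALSE)
    }
    s <- toupper(as.character(Rsamtools::scanFa(fa, idx[hit])[[1L]]))
    assign(contig, s, envir = cache)
    s
  }
  structure(list(fetch = fetch, source = path), class = "ref_genome")
}

as_ref_genome <- function(reference) {
  if (is.null(reference) || inherits(reference, "ref_genome")) {
    return(reference)
  }
  open_reference(reference)
}

# Map one auxiliary tag value to a strand class; NA when unrecognized.
tag_value_strand <- function(tag, value) {
  out <- rep(NA_character_, length(value))
  known <- switch(tag,
    YD = c(f = STRAND_TOP, r = STRAND_BOTTOM), # BISCUIT / bwa-meth
    XG = c(CT = STRAND_TOP, GA = STRAND_BOTTOM), # Bismark
    XB = c(C = STRAND_TOP, G = STRAND_BOTTOM), # gemBS
    stop("unrecognized strand tag: ", tag, call. = FALSE)
  )
  hit <- !is.na(value) & value %in% names(known)
  out[hit] <- known[value[hit]]
  out
}

#' Strand class from aligner auxiliary tags
#'
#' Inspects the two primary records of each template for strand tags in
#' priority order (default `YD` then `XG` then `XB`). The first tag
#' present on either mate decides; if the mates carry conflicting values
#' for that tag the template is `UNKNOWN` (a fragment has one strand of
#' origin, so disagreement signals aligner inconsistency). Unrecognized
#' values are treated as absent.
#'
#' @param tags1,tags2 `tags` strings of the primary read-1 and read-2
#'   records (`NA` when the record or its tags are absent).
#' @param tag_priority Character vector of tags to try, in order.
#' @return Character vector of `"TOP"`, `"BOTTOM"`, or `"UNKNOWN"`.
#' @export
strand_from_tags <- function(tags1, tags2 = NA_character_,
                             tag_priority = c("YD", "XG", "XB")) {
  n <- max(length(tags1), length(tags2))
  tags1 <- rep_len(tags1, n)
  tags2 <- rep_len(tags2, n)
  out <- rep(STRAND_UNKNOWN, n)
  decided <- rep(FALSE, n)
  for (tag in tag_priority) {
    s1 <- tag_value_strand(tag, sam_tag(tags1, tag))
    s2 <- tag_value_strand(tag, sam_tag(tags2, tag))
    present <- !decided & (!is.na(s1) | !is.na(s2))
    if (!any(present)) next
    conflict <- present & !is.na(s1) & !is.na(s2) & s1 != s2
    agree <- present & !conflict
    out[agree] <- dplyr::coalesce(s1[agree], s2[agree])
    out[conflict] <- STRAND_UNKNOWN
    decided <- decided | present
  }
  out
}

#' Count bisulfite conversion evidence in one record
#'
#' Walks the aligned (M/=/X) columns of a mapped record and counts
#' reference-C read-T mismatches (`ct`, top-strand evidence) and
#' reference-G read-A mismatches (`ga`, bottom-strand evidence).
#' Soft/hard-clipped, inserted, and deleted columns are skipped;
#' comparison is case-insensitive and N bases are never counted.
#'
#' @param rname,pos,cigar,seq Mandatory fields of one mapped record
#'   (`pos` is 1-based SAM POS).
#' @param reference A `ref_genome` from [open_reference()].
#' @return Named numeric vector `c(ct = , ga = )`.
#' @export
count_conversions <- function(rname, pos, cigar, seq, reference) {
  reference <- as_ref_genome(reference)
  contig <- reference$fetch(rname)
  ops <- cigar_ops(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  if (qlen != nchar(seq)) {
    stop(
      "CIGAR (", cigar, ") implies a ", qlen,
      " bp sequence but SEQ has ", nchar(seq), " bp",
      call. = FALSE
    )
  }
  rpos <- pos # 1-based on reference
  qpos <- 1L
  ref_parts <- character()
  read_parts <- character()
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]
    len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      if (rpos + len - 1 > nchar(contig)) {
        stop("alignment runs off the end of contig ", rname, call. = FALSE)
      }
      ref_parts <- c(ref_parts, substr(contig, rpos, rpos + len - 1))
      read_parts <- c(read_parts, substr(seq, qpos, qpos + len - 1L))
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } # H, P consume nothing
  }
  r <- charToRaw(paste(ref_parts, collapse = ""))
  q <- charToRaw(toupper(paste(read_parts, collapse = "")))
  c(
    ct = sum(r == charToRaw("C") & q == charToRaw("T")),
    ga = sum(r == charToRaw("G") & q == charToRaw("A"))
  )
}

#' Strand class from conversion counts
#'
#' Sums conversion evidence over the mapped primary records of a template
#' (both mates derive from one fragment) and calls `TOP` when C->T
#' conversions outnumber G->A, `BOTTOM` when G->A outnumber C->T. Ties —
#' including zero evidence — resolve to `TOP`: a tie carries no
#' information, and a fixed deterministic choice merely files the
#' ambiguous template consistently into one class.
#'
#' @param records A data frame of the template's mapped primary records
#'   with columns `rname`, `pos`, `cigar`, `seq`.
#' @param reference A `ref_genome` or FASTA path.
#' @return `"TOP"` or `"BOTTOM"`.
#' @export
strand_from_conversions <- function(records, reference) {
  reference <- as_ref_genome(reference)
  tot <- c(ct = 0, ga = 0)
  for (i in seq_len(nrow(records))) {
    tot <- tot + count_conversions(
      records$rname[i], records$pos[i], records$cigar[i], records$seq[i],
      reference
    )
  }
  if (tot[["ga"]] > tot[["ct"]]) STRAND_BOTTOM else STRAND_TOP
}

#' Infer the bisulfite strand class of each template
#'
#' The per-template strand call used by the dedup engine, exposed as its
#' own verb. In `wgs` mode every template is assigned the single `TOP`
#' class (all reads are assumed to derive from the same original strand).
#' In `bisulfite` mode aligner tags are consulted first
#' ([strand_from_tags()]); templates still `UNKNOWN` fall back to
#' conversion counting against the reference when one is supplied, and to
#' `TOP` (counted in `source = "default"`) otherwise.
#'
#' @param sam A `sam_tbl` of name-grouped records.
#' @param reference Optional `ref_genome`, FASTA path, or `DNAStringSet`.
#' @param mode `"bisulfite"` or `"wgs"`.
#' @param tag_priority Strand tags to try, in order.
#' @return A tibble with one row per template: `qname`, `strand`, and
#'   `source` (`"tag"`, `"conversion"`, `"default"`, or `"wgs"`).
#' @export
infer_strand <- function(sam, reference = NULL, mode = c("bisulfite", "wgs"),
                         tag_priority = c("YD", "XG", "XB")) {
  mode <- match.arg(mode)
  tid <- check_name_grouped(sam$qname)
  n_t <- if (nrow(sam)) max(tid) else 0L
  qname_t <- sam$qname[!duplicated(tid)]
  if (mode == "wgs") {
    return(tibble::tibble(
      qname = qname_t, strand = rep(STRAND_TOP, n_t),
      source = rep("wgs", n_t)
    ))
  }
  reference <- as_ref_genome(reference)
  primary <- !has_flag(sam$flag, FLAG_SECONDARY) &
    !has_flag(sam$flag, FLAG_SUPPLEMENTARY)
  paired <- has_flag(sam$flag, FLAG_PAIRED)
  isr1 <- primary & (!paired | has_flag(sam$flag, FLAG_READ1))
  isr2 <- primary & paired & has_flag(sam$flag, FLAG_READ2)
  r1 <- r2 <- rep(NA_integer_, n_t)
  r1[tid[isr1]] <- which(isr1)
  r2[tid[isr2]] <- which(isr2)
  tags_at <- function(i) ifelse(is.na(i), NA_character_, sam$tags[pmax(i, 1L)])
  strand <- strand_from_tags(tags_at(r1), tags_at(r2), tag_priority)
  source <- ifelse(strand == STRAND_UNKNOWN, "default", "tag")
  unknown <- which(strand == STRAND_UNKNOWN)
  if (length(unknown) && !is.null(reference)) {
    mapped <- !has_flag(sam$flag, FLAG_UNMAPPED)
    for (t in unknown) {
      idx <- c(r1[t], r2[t])
      idx <- idx[!is.na(idx) & mapped[idx]]
      if (length(idx) == 0L) next # stays default
      strand[t] <- strand_from_conversions(sam[idx, ], reference)
      source[t] <- "conversion"
    }
  }
  strand[strand == STRAND_UNKNOWN] <- STRAND_TOP
  tibble::tibble(qname = qname_t, strand = strand, source = source)
}
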