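#' Read a SAM or BAM file into a tibble
#'
#' One row per alignment record, in file order. The eleven mandatory SAM
#' fields become columns; auxiliary tags are kept verbatim as a single
#' tab-joined `tags` column so that records round-trip byte-identically.
#' The header lines are attached as the `"header"` attribute. BAM input is
#' decoded through `samtools view -h`; `"-"` reads SAM from standard input.
#'
#' Fields that the engine never edits (`mapq`, `rnext`, `pnext`, `tlen`)
#' are kept as character columns; `flag` and `pos` are integers (`pos` is
#' the 1-based SAM POS; 0 for unmapped records).
#'
#' @param path Path to a `.sam` or `.bam` file, or `"-"` for stdin.
#' @return A tibble of class `sam_tbl` with attribute `header`.
#' @export
#' @examples
#' sam <- read_sam(system.file("extdata", "toy.sam", package = "bsmarkdup"))
#' dplyr::count(sam, mapped = !bitwAnd(flag, 0x4))
read_sam <- function(path) {
  lines <- read_sam_lines(path)
  is_hdr <- startsWith(lines, "@")
  # header must be a prefix of the file
  if (any(is_hdr) && any(!is_hdr) && max(which(is_hdr)) > min(which(!is_hdr))) {
    stop("header line found after alignment records", call. = FALSE)
  }
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  sam <- parse_sam_records(body)
  if (any(sam$rname != "*") && !any(startsWith(header, "@SQ"))) {
    stop("input has mapped records but no @SQ header lines", call. = FALSE)
  }
  new_sam_tbl(sam, header)
}

new_sam_tbl <- function(records, header) {
  out <- tibble::as_tibble(records)
  attr(out, "header") <- header
  class(out) <- c("sam_tbl", class(out))
  out
}

parse_sam_records <- function(body) {
  if (length(body) == 0L) {
    return(tibble::tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = character(), cigar = character(),
      rnext = character(), pnext = character(), tlen = character(),
      seq = character(), qual = character(), tags = character()
    ))
  }
  sp <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(sp)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1L],
      " of the alignment section (fewer than 11 fields)",
      call. = FALSE
    )
  }
  fld <- function(i) vapply(sp, `[[`, character(1), i)
  tags <- vapply(sp, function(x) {
    if (length(x) > 11L) paste(x[12:length(x)], collapse = "\t") else NA_character_
  }, character(1))
  flag <- suppressWarnings(as.integer(fld(2)))
  pos <- suppressWarnings(as.integer(fld(4)))
  if (anyNA(flag) || anyNA(pos)) {
    stop("non-numeric FLAG or POS field in SAM input", call. = FALSE)
  }
  tibble::tibble(
    qname = fld(1), flag = flag, rname = fld(3), pos = pos,
    mapq = fld(5), cigar = fld(6), rnext = fld(7), pnext = fld(8),
    tlen = fld(9), seq = fld(10), qual = fld(11), tags = tags
  )
}

read_sam_lines <- function(path) {
  if (identical(path, "-")) {
    return(readLines(file("stdin")))
  }
  if (!file.exists(path)) stop("cannot read alignment input: ", path, call. = FALSE)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    con <- pipe(paste("samtools view -h", shQuote(path)))
    on.exit(close(con), add = TRUE)
    lines <- tryCatch(readLines(con), error = function(e) {
      stop("failed to decode BAM (truncated or invalid): ", path, call. = FALSE)
    })
    return(lines)
  }
  readLines(path)
}

#' Get or parse the header of a SAM tibble
#'
#' @param sam A `sam_tbl` as returned by [read_sam()].
#' @return `sam_header()`: the character vector of header lines.
#'   `sam_contigs()`: a tibble with `name` and `length`, in `@SQ` order.
#' @export
sam_header <- function(sam) {
  attr(sam, "header") %||% character()
}

#' @rdname sam_header
#' @export
sam_contigs <- function(sam) {
  header <- if (is.character(sam)) sam else sam_header(sam)
  sq <- header[startsWith(header, "@SQ")]
  name <- sam_hdr_field(sq, "SN")
  len <- suppressWarnings(as.numeric(sam_hdr_field(sq, "LN")))
  if (length(sq) && (anyNA(name) || anyNA(len))) {
    stop("@SQ line missing SN or LN field", call. = FALSE)
  }
  tibble::tibble(name = name, length = len)
}

sam_hdr_field <- function(lines, key) {
  m <- regexpr(paste0("\t", key, ":([^\t]*)"), lines, perl = TRUE)
  out <- rep(NA_character_, length(lines))
  hit <- m != -1L
  if (any(hit)) {
    st <- attr(m, "capture.start")[hit, 1L]
    ln <- attr(m, "capture.length")[hit, 1L]
    out[hit] <- substr(lines[hit], st, st + ln - 1L)
  }
  out
}

#' Write a SAM tibble to SAM or BAM
#'
#' Serializes the header and records. Output format follows the file
#' extension (`.bam` encodes through `samtools view -b`); `"-"` writes SAM
#' to standard output. An optional `@PG` line is appended to the header to
#' record provenance.
#'
#' @param sam A `sam_tbl`.
#' @param path Output path, or `"-"` for stdout.
#' @param pg Optional single `@PG` header line to append (see
#'   [sam_pg_line()]), or `NULL` for none.
#' @param format `"auto"` (by extension), `"sam"`, or `"bam"`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path, pg = NULL, format = c("auto", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (!identical(path, "-") && grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "sam"
  }
  header <- sam_header(sam)
  if (!is.null(pg)) header <- c(header, pg)
  lines <- c(header, serialize_sam_records(sam))
  if (identical(path, "-")) {
    writeLines(lines, stdout())
  } else if (format == "bam") {
    con <- pipe(paste("samtools view -b -o", shQuote(path), "-"), "w")
    writeLines(lines, con)
    close(con)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

serialize_sam_records <- function(sam) {
  if (nrow(sam) == 0L) {
    return(character())
  }
  base <- paste(
    sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq, sam$cigar,
    sam$rnext, sam$pnext, sam$tlen, sam$seq, sam$qual,
    sep = "\t"
  )
  ifelse(is.na(sam$tags), base, paste(base, sam$tags, sep = "\t"))
}

#' Build a @PG header line for provenance
#'
#' @param cl The command line to record.
#' @return A single `@PG` header line naming this tool and its version.
#' @export
sam_pg_line <- function(cl = "") {
  ver <- as.character(utils::packageVersion("bsmarkdup"))
  paste0("@PG\tID:bsmarkdup\tPN:bsmarkdup\tVN:", ver, "\tCL:", cl)
}

#' Check that a record stream is name-grouped
#'
#' Records sharing a QNAME must be contiguous (aligner output order or a
#' queryname sort). A QNAME that reappears after its group has closed —
#' the signature of coordinate-sorted input — is a fatal error, because
#' the duplicate signature needs both primary mates of a template at once.
#'
#' @param qname Character vector of QNAMEs in stream order.
#' @return Invisibly, an integer vector of template ids (1-based, in
#'   first-appearance order).
#' @export
check_name_grouped <- function(qname) {
  r <- rle(qname)
  if (anyDuplicated(r$values)) {
    bad <- r$values[duplicated(r$values)][1L]
    stop(
      "input not name-grouped: QNAME '", bad,
      "' reappears after its group closed; provide aligner output order ",
      "or queryname-sorted input (coordinate-sorted input is not accepted)",
      call. = FALSE
    )
  }
  invisible(rep.int(seq_along(r$lengths), r$lengths))
}
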