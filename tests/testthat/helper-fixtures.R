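# Build a sam_tbl from SAM text lines (tab-separated, no trailing newline).
sam_from_text <- function(..., contigs = c(chr1 = 500L, chr2 = 400L)) {
  header <- c(
    "@HD\tVN:1.6\tGO:query",
    paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs)
  )
  path <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame())
  writeLines(c(header, unlist(list(...))), path)
  read_sam(path)
}

# One SAM record line from named fields with sensible defaults.
sam_line <- function(qname, flag, rname = "chr1", pos = 100L, mapq = "60",
                     cigar = "50M", rnext = "*", pnext = "0", tlen = "0",
                     seq = strrep("A", 50), qual = NULL, tags = NULL) {
  qual <- qual %||% strrep("I", nchar(seq))
  base <- paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
    seq, qual,
    sep = "\t"
  )
  if (is.null(tags)) base else paste(base, paste(tags, collapse = "\t"), sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A co-located PE duplicate pair (t_a first, t_b identical) plus controls.
pe_pair_lines <- function(qname, pos1 = 11L, pos2 = 161L, tag = "YD:Z:f",
                          rname = "chr1", extra_tags = NULL) {
  tags <- c(tag, extra_tags)
  c(
    sam_line(qname, 99L, rname, pos1,
      cigar = "50M", rnext = "=",
      pnext = pos2, tlen = "200", tags = tags
    ),
    sam_line(qname, 147L, rname, pos2,
      cigar = "50M", rnext = "=",
      pnext = pos1, tlen = "-200", tags = tags
    )
  )
}

# Records as a plain data frame, header attribute dropped (for comparing
# runs whose @PG provenance lines legitimately differ).
records_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "header") <- NULL
  x
}

# Sorted QNAMEs of the templates a run marked as duplicates.
marked_qnames <- function(res) {
  t <- tidy(res)
  sort(t$qname[t$duplicate])
}

# Environment variable string so a spawned Rscript sees this test library.
test_rlibs <- function() {
  paste(.libPaths(), collapse = .Platform$path.sep)
}

cli_path <- function() {
  file.path(find.package("bsmarkdup"), "exec", "bsmarkdup")
}
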