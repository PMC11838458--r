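FRAGMENT_COLS <- c("transcript_id", "start", "end", "umi", "dup_group_size",
                   "read1_gc", "unique_mapping")

#' Read and write fragment tables
#'
#' The package's fragment-table dialect is a TSV with columns
#' `transcript_id`, `start`, `end` (0-based half-open transcript
#' coordinates), and optionally `umi`, `dup_group_size`, `read1_gc`,
#' `unique_mapping`. One row is one (possibly still duplicated) sequenced
#' fragment.
#'
#' @param path TSV path.
#' @return Data frame of fragment records.
#' @export
read_fragments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("transcript_id", "start", "end"), names(df))
  if (base::length(missing) > 0L)
    stop2("fragment table lacks columns: ", paste(missing, collapse = ", "))
  if (!is.null(df$unique_mapping)) df$unique_mapping <- as.logical(df$unique_mapping)
  df
}

#' @rdname read_fragments
#' @param fragments Fragment data frame.
#' @export
write_fragments <- function(fragments, path) {
  keep <- intersect(FRAGMENT_COLS, names(fragments))
  write.table(fragments[, keep, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract fragment records from transcriptome alignments
#'
#' Reads properly paired alignments against a transcriptome reference (SAM or
#' BAM; SAM is converted on the fly) and reduces each proper pair to one
#' fragment record spanning from the leftmost mapped base to
#' `leftmost + TLEN` (soft-clipped bases are outside that span by
#' construction). UMIs are taken from the read-name suffix after the last
#' `_`, following the umi_tools convention, when `umi_from_name` is set.
#' Uniqueness is taken from the `NH` tag when present.
#'
#' @param path SAM or BAM file of transcriptome alignments (no junctions).
#' @param umi_from_name Parse the UMI from the read name (default `TRUE`).
#' @return Fragment data frame (one row per pair) with `read1_gc` computed
#'   from the first read's sequence.
#' @export
read_fragments_bam <- function(path, umi_from_name = TRUE) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE,
                                 isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "mpos", "isize", "seq"),
    tag = "NH")
  res <- Rsamtools::scanBam(path, param = par)[[1]]
  n <- base::length(res$qname)
  if (n == 0L) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), umi = character(0),
                      read1_gc = numeric(0), unique_mapping = logical(0)))
  }
  # TLEN spans leftmost to rightmost mapped base of the pair
  start <- pmin(res$pos, res$mpos) - 1L
  end <- start + abs(res$isize)
  gc <- vapply(as.character(res$seq), function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C", "g", "c"))
  }, numeric(1), USE.NAMES = FALSE)
  umi <- if (umi_from_name) sub("^.*_", "", res$qname) else NA_character_
  nh <- res$tag$NH
  uniq <- if (is.null(nh)) rep(TRUE, n) else (is.na(nh) | nh == 1L)
  df <- data.frame(transcript_id = as.character(res$rname),
                   start = as.integer(start), end = as.integer(end),
                   umi = umi, read1_gc = gc, unique_mapping = uniq,
                   stringsAsFactors = FALSE)
  df[df$end > df$start, , drop = FALSE]
}

#' Write a coverage track as bedGraph
#'
#' Transcript-space bedGraph: runs of equal coverage become intervals
#' (0-based half-open).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  v <- track_values(track)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-base::length(ends)])
  tid <- if (inherits(track, "CoverageTrack")) track$transcript_id else "track"
  df <- data.frame(tid, starts, ends, r$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
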