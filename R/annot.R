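#' Transcript models
#'
#' A `TranscriptModel` describes one single-isoform gene: its exon structure
#' on the genome and the derived transcript-space length. All internal
#' coordinates are 0-based half-open; GTF input (1-based closed) is converted
#' at the single parsing point in [load_annotation()].
#'
#' @param gene_id,transcript_id,chrom,biotype Identifiers and gene biotype.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`) of 0-based half-open
#'   genomic intervals; they are sorted and must not overlap.
#' @param sequence_ref Name under which the transcript sequence is found in
#'   the FASTA / sequence set (defaults to `transcript_id`).
#' @return An object of class `TranscriptModel` with a `length` field equal to
#'   the summed exon lengths.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             biotype = "protein_coding",
                             sequence_ref = transcript_id) {
  if (!strand %in% c("+", "-")) stop2("strand must be '+' or '-'")
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) stop2("empty or inverted exon")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop2("overlapping exons in ", transcript_id)
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons,
         length = sum(exons[, 2L] - exons[, 1L]),
         biotype = biotype, sequence_ref = sequence_ref),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("<TranscriptModel> %s/%s %s:%s %d exon(s), length %d, %s\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand,
              nrow(x$exons), x$length, x$biotype))
  invisible(x)
}

# Light structural scan so malformed GTF lines are reported with their line
# number before the real parser runs.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  bad <- which(body)[vapply(lines[body], function(l) {
    base::length(strsplit(l, "\t", fixed = TRUE)[[1]]) < 9L
  }, logical(1))]
  if (base::length(bad) > 0L) {
    stop2(sprintf("malformed GTF line %d in %s: fewer than 9 tab-separated fields",
                  bad[1], path))
  }
  invisible(TRUE)
}

#' Load single-isoform transcript models from a GTF
#'
#' Reads an Ensembl-dialect GTF (needs `gene_id`, `transcript_id`,
#' `gene_biotype` attributes on exon features) and returns one
#' [transcript_model()] per gene that has exactly one annotated transcript.
#' Genes with several isoforms are excluded entirely, so downstream coverage
#' non-uniformity cannot reflect isoform mixtures. Exons are merged per
#' transcript and coordinates converted from GTF 1-based closed to the
#' package's 0-based half-open convention.
#'
#' @param gtf_source Path to a GTF file.
#' @return Named list of `TranscriptModel` objects (names = gene_id).
#' @export
load_annotation <- function(gtf_source) {
  validate_gtf_lines(gtf_source)
  gr <- rtracklayer::import(gtf_source, format = "gtf")
  ex <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (base::length(ex) == 0L) stop2("no exon features in ", gtf_source)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start0 = GenomicRanges::start(ex) - 1L,
    end0 = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    biotype = if (!is.null(ex$gene_biotype)) as.character(ex$gene_biotype)
              else NA_character_,
    stringsAsFactors = FALSE)

  tx_per_gene <- tapply(df$transcript_id, df$gene_id,
                        function(t) base::length(unique(t)))
  single <- names(tx_per_gene)[tx_per_gene == 1L]
  df <- df[df$gene_id %in% single, , drop = FALSE]

  models <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("transcript ", tid, " has zero exons; skipped")
      next
    }
    # merge any touching/overlapping exon records
    ir <- IRanges::reduce(IRanges::IRanges(sub$start0 + 1L, sub$end0))
    exons <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    models[[sub$gene_id[1]]] <- transcript_model(
      gene_id = sub$gene_id[1], transcript_id = tid,
      chrom = sub$chrom[1], strand = sub$strand[1],
      exons = exons, biotype = sub$biotype[1])
  }
  models
}

#' Select the analysis gene set
#'
#' Applies the standard eligibility filter -- transcript length between
#' 600 and 7000 bases inclusive, biotype `protein_coding` or `lncRNA`,
#' single annotated isoform (guaranteed by [load_annotation()]) -- and keeps
#' the `n` most highly expressed survivors. Expression is a deduplicated
#' fragment count per gene; ties are broken by lexicographic gene_id so the
#' selection is deterministic.
#'
#' @param models Named list of [transcript_model()] objects.
#' @param expression Named numeric vector of fragment counts per gene_id;
#'   genes absent from it count as 0.
#' @param n Number of genes to keep.
#' @param min_len,max_len Inclusive transcript-length bounds.
#' @param biotypes Eligible biotypes.
#' @return Ordered list of `TranscriptModel` (highest expression first). If
#'   fewer than `n` genes survive the filters, all survivors are returned with
#'   a warning.
#' @export
select_genes <- function(models, expression, n = 100,
                         min_len = 600, max_len = 7000,
                         biotypes = c("protein_coding", "lncRNA")) {
  if (base::length(models) == 0L) stop2("empty model set")
  stopifnot(is_count(n), n >= 1)
  ok <- vapply(models, function(m) {
    m$length >= min_len && m$length <= max_len &&
      (is.na(m$biotype) == FALSE && m$biotype %in% biotypes)
  }, logical(1))
  surv <- models[ok]
  if (base::length(surv) == 0L) {
    warning("no genes survive the filters")
    return(list())
  }
  ids <- vapply(surv, `[[`, "", "gene_id")
  counts <- ifelse(ids %in% names(expression), expression[ids], 0)
  counts[is.na(counts)] <- 0
  ord <- order(-counts, ids)
  surv <- surv[ord]
  if (base::length(surv) < n) {
    warning(sprintf("only %d genes survive the filters (requested %d)",
                    base::length(surv), n))
    return(surv)
  }
  surv[seq_len(n)]
}

#' Project a genomic fragment into transcript coordinates
#'
#' Maps a 0-based half-open genomic interval through the exon concatenation of
#' a transcript model. On the minus strand, transcript position 0 is the 5'
#' end (the rightmost genomic exon base). Interior introns between the two
#' endpoints are removed: the fragment is treated as contiguous in transcript
#' space. Fragments with either endpoint in an intron or outside the gene are
#' rejected (`NULL`), not clipped.
#'
#' @param genomic_start,genomic_end 0-based half-open genomic coordinates on
#'   `model$chrom`.
#' @param model A [transcript_model()].
#' @return Numeric `c(start, end)` in 0-based half-open transcript
#'   coordinates, or `NULL`.
#' @export
project_fragment <- function(genomic_start, genomic_end, model) {
  if (genomic_start >= genomic_end) stop2("start must be < end")
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  before <- cumsum(c(0, widths))[seq_len(nrow(ex))]
  map_pos <- function(g) {
    i <- which(g >= ex[, 1L] & g < ex[, 2L])
    if (base::length(i) != 1L) return(NA_real_)
    before[i] + (g - ex[i, 1L])
  }
  tp_start <- map_pos(genomic_start)
  tp_last <- map_pos(genomic_end - 1)
  if (is.na(tp_start) || is.na(tp_last)) return(NULL)
  if (model$strand == "+") {
    unname(c(tp_start, tp_last + 1))
  } else {
    L <- model$length
    unname(c(L - tp_last - 1, L - tp_start))
  }
}

#' Write the selected-gene table
#'
#' @param models Ordered list of [transcript_model()] (see [select_genes()]).
#' @param expression Named fragment counts used for the ranking.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(models, expression, path) {
  ids <- vapply(models, `[[`, "", "gene_id")
  df <- data.frame(
    gene_id = ids,
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    length = vapply(models, `[[`, 0, "length"),
    count = ifelse(ids %in% names(expression), expression[ids], 0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
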