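# Shared fixtures built in code.

planted_pwm <- function(fav = 0.29, width = 12) {
  m <- matrix((1 - fav) / 3, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) m[((j - 1) %% 4) + 1, j] <- fav
  m
}

random_seq <- function(L, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
}

# small simulated library -> deduplicated fragments + per-gene tracks
quick_library <- function(cfg) {
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(cfg, tx$models, tx$sequences)
  dd <- dedup_fragments(sim$fragments)
  tracks <- lapply(tx$models, function(m)
    fragment_coverage(dd[dd$transcript_id == m$transcript_id, , drop = FALSE],
                      m$length, m$transcript_id))
  list(tx = tx, sim = sim, dedup = dd, tracks = tracks)
}

# hand-built toy GTF text for annotation tests
toy_gtf_lines <- function() {
  a <- function(g, t, bt) sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";', g, t, bt)
  c(
    "#!genome-version toy",
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", a("gA", "gA.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", a("gA", "gA.t1", "protein_coding"), sep = "\t"),
    # gene with two isoforms: excluded
    paste("chr1", "src", "exon", 1001, 1400, ".", "+", ".", a("gB", "gB.t1", "protein_coding"), sep = "\t"),
    paste("chr1", "src", "exon", 1001, 1200, ".", "+", ".", a("gB", "gB.t2", "protein_coding"), sep = "\t"),
    # minus-strand single-isoform lncRNA
    paste("chr2", "src", "exon", 501, 900, ".", "-", ".", a("gC", "gC.t1", "lncRNA"), sep = "\t")
  )
}
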