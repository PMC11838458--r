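# Independent brute-force oracles used to check the package's optimized
# implementations. These deliberately share no code with R/.

# per-base overlap counting, O(n * L)
oracle_coverage <- function(st, en, L) {
  v <- numeric(L)
  for (i in seq_along(st)) {
    for (p in seq.int(st[i], en[i] - 1L)) v[p + 1L] <- v[p + 1L] + 1
  }
  v
}

# water between two bounding maxima (0-based) by per-base scan
oracle_water <- function(v, l, r) {
  lvl <- min(v[l + 1L], v[r + 1L])
  s <- 0
  for (i in seq.int(l + 1L, r - 1L)) s <- s + max(0, lvl - v[i + 1L])
  s
}

# per-position duplicate-rate scan
oracle_dupe_rate <- function(df, L) {
  vapply(seq_len(L) - 1L, function(p) {
    ov <- df$start <= p & p < df$end
    if (!any(ov)) return(NA_real_)
    mean(df$dup_group_size[ov] >= 2)
  }, numeric(1))
}

# sliding-window exact placement count (probe + reverse complement,
# palindrome counted once)
oracle_count_placements <- function(probe, refs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(probe, "")[[1]]]), collapse = "")
  pats <- unique(c(probe, rc))
  total <- 0L
  w <- nchar(probe)
  for (s in refs) {
    L <- nchar(s)
    if (L < w) next
    for (off in seq_len(L - w + 1L)) {
      if (substr(s, off, off + w - 1L) %in% pats) total <- total + 1L
    }
  }
  total
}

# two-sided Fisher p by explicit hypergeometric enumeration with choose()
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  sup <- seq.int(max(0, k - n), min(k, m))
  pr <- choose(m, sup) * choose(n, k - sup) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# dense renormalized-boundary Gaussian convolution
oracle_smooth <- function(x, sigma) {
  h <- ceiling(4 * sigma)
  k <- dnorm(seq.int(-h, h), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- max(1, i - h):min(n, i + h)
    w <- k[js - i + h + 1L]
    out[i] <- sum(x[js] * w) / sum(w)
  }
  out
}

# line-by-line GTF parser used as the annotation oracle: returns per
# single-isoform gene a list(transcript_id, strand, biotype, length, exons)
oracle_parse_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  attr1 <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    if (length(m) == 0) NA_character_ else sub(paste0(key, ' "([^"]*)"'), "\\1", m)
  }
  ex <- Filter(function(r) r[3] == "exon", recs)
  df <- do.call(rbind, lapply(ex, function(r) {
    data.frame(gene = attr1(r[9], "gene_id"), tx = attr1(r[9], "transcript_id"),
               bt = attr1(r[9], "gene_biotype"), chrom = r[1], strand = r[7],
               s = as.integer(r[4]) - 1L, e = as.integer(r[5]),
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, ]
    if (length(unique(sub$tx)) != 1L) next
    sub <- sub[order(sub$s), ]
    # merge overlapping/adjacent
    ex2 <- list(c(sub$s[1], sub$e[1]))
    for (i in seq_len(nrow(sub))[-1]) {
      last <- ex2[[length(ex2)]]
      if (sub$s[i] <= last[2]) {
        ex2[[length(ex2)]] <- c(last[1], max(last[2], sub$e[i]))
      } else ex2[[length(ex2) + 1L]] <- c(sub$s[i], sub$e[i])
    }
    em <- do.call(rbind, ex2)
    out[[g]] <- list(transcript_id = sub$tx[1], strand = sub$strand[1],
                     biotype = sub$bt[1], chrom = sub$chrom[1],
                     length = sum(em[, 2] - em[, 1]), exons = em)
  }
  out
}
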