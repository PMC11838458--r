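#' Fragment-end position weight matrices
#'
#' Random-hexamer priming during reverse transcription leaves a sequence
#' preference at fragment ends. An `EndPWM` is the empirical per-position
#' base-frequency model of the first (fragment_start) or last (fragment_end)
#' `width` bases of sequenced fragments, pseudocounted so every entry is
#' positive.
#'
#' @param freqs 4 x width matrix (rows A,C,G,T), each column a probability
#'   vector.
#' @param side `"fragment_start"` or `"fragment_end"`.
#' @param n_fragments Fragments the matrix was built from.
#' @param pseudocount Pseudocount added per cell before normalization.
#' @return An object of class `EndPWM`.
#' @export
end_pwm <- function(freqs, side = c("fragment_start", "fragment_end"),
                    n_fragments = NA_integer_, pseudocount = 1) {
  side <- match.arg(side)
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L) stop2("`freqs` must have 4 rows (A,C,G,T)")
  rownames(freqs) <- BASES
  csum <- colSums(freqs)
  if (any(abs(csum - 1) > 1e-9)) stop2("PWM columns must sum to 1")
  if (any(freqs <= 0)) stop2("PWM entries must be positive (pseudocounted)")
  structure(list(side = side, freqs = freqs, n_fragments = n_fragments,
                 pseudocount = pseudocount),
            class = "EndPWM")
}

#' @export
print.EndPWM <- function(x, ...) {
  cat(sprintf("<EndPWM %s> width %d, n_fragments %s\n",
              x$side, ncol(x$freqs), format(x$n_fragments)))
  invisible(x)
}

uniform_pwm <- function(side, width = 12) {
  end_pwm(matrix(0.25, 4, width), side = side, pseudocount = 0.25)
}

#' Build empirical fragment-end PWMs
#'
#' Tallies the first and last `width` bases of every fragment (in transcript
#' orientation, 5' to 3') into a start PWM and an end PWM. Counts get a
#' pseudocount per cell and are column-normalized. Fragments shorter than
#' `width` or containing a non-ACGT base in either window are skipped.
#'
#' @param fragments Fragment data frame (`transcript_id`, 0-based `start`,
#'   `end`).
#' @param sequences Transcript sequences: named character vector,
#'   `DNAStringSet`, or FASTA path, in transcript orientation.
#' @param width PWM width in bases (default 12).
#' @param pseudocount Pseudocount per cell (default 1).
#' @return List with elements `start_pwm` and `end_pwm` ([end_pwm()]
#'   objects).
#' @export
build_pwms <- function(fragments, sequences, width = 12, pseudocount = 1) {
  sequences <- as_sequence_set(sequences)
  counts_s <- matrix(0, 4, width, dimnames = list(BASES, NULL))
  counts_e <- matrix(0, 4, width, dimnames = list(BASES, NULL))
  n_used <- 0L
  for (tid in unique(fragments$transcript_id)) {
    seq <- sequences[[tid]]
    if (is.null(seq) || is.na(seq)) stop2("no sequence for transcript ", tid)
    b <- base_codes(seq)
    fr <- fragments[fragments$transcript_id == tid, , drop = FALSE]
    fr <- fr[fr$end - fr$start >= width, , drop = FALSE]
    if (nrow(fr) == 0L) next
    # windows as n x width matrices of base codes
    offs <- seq_len(width) - 1L
    win_s <- matrix(b[outer(fr$start + 1L, offs, `+`)], ncol = width)
    win_e <- matrix(b[outer(fr$end - width + 1L, offs, `+`)], ncol = width)
    ok <- !(rowSums(is.na(win_s)) > 0L | rowSums(is.na(win_e)) > 0L)
    if (!any(ok)) next
    win_s <- win_s[ok, , drop = FALSE]
    win_e <- win_e[ok, , drop = FALSE]
    n_used <- n_used + sum(ok)
    for (j in seq_len(width)) {
      counts_s[, j] <- counts_s[, j] + tabulate(win_s[, j], nbins = 4L)
      counts_e[, j] <- counts_e[, j] + tabulate(win_e[, j], nbins = 4L)
    }
  }
  if (n_used == 0L) stop2("no usable fragments for PWM construction")
  norm <- function(cn) sweep(cn + pseudocount, 2, colSums(cn + pseudocount), `/`)
  list(start_pwm = end_pwm(norm(counts_s), "fragment_start", n_used, pseudocount),
       end_pwm = end_pwm(norm(counts_e), "fragment_end", n_used, pseudocount))
}

# Log2-likelihood of every width-window of a base-code vector under a PWM.
# Returns a vector W where W[p] is the log2-likelihood of the window starting
# at (1-based) position p; length L - width + 1. NA where the window holds a
# non-ACGT base.
window_loglik <- function(codes, pwm) {
  lp <- log2(pwm$freqs)
  w <- ncol(lp)
  L <- base::length(codes)
  if (L < w) return(numeric(0))
  np <- L - w + 1L
  s <- numeric(np)
  for (j in seq_len(w)) {
    cj <- codes[j:(np + j - 1L)]
    s <- s + lp[cj + (j - 1L) * 4L]  # lp[cj, j] by linear index
  }
  s
}

#' Composite start-minus-end PWM score along a transcript
#'
#' For every inter-base boundary, scores how strongly the local sequence
#' favors fragments *starting* just 3' of the boundary versus fragments
#' *ending* just 5' of it: the log2-likelihood of the next `width` bases
#' under the start PWM minus the log2-likelihood of the previous `width`
#' bases under the end PWM. This approximates the expected change in coverage
#' across the boundary.
#'
#' @param start_pwm,end_pwm [end_pwm()] objects of equal width.
#' @param sequence One transcript sequence (character scalar).
#' @return Numeric vector `score` of length `nchar(sequence)`; `score[p]`
#'   (1-based) is the propensity for fragments to start at position p minus
#'   the propensity to end at position p-1. Entries are `NA` (the undefined
#'   marker) where either window leaves the sequence or contains a non-ACGT
#'   base; defined entries span p = width+1 .. L-width+1.
#' @export
composite_scores <- function(start_pwm, end_pwm, sequence) {
  w <- ncol(start_pwm$freqs)
  if (ncol(end_pwm$freqs) != w) stop2("PWM widths differ")
  codes <- base_codes(toupper(sequence))
  L <- base::length(codes)
  out <- rep(NA_real_, L)
  if (L < 2L * w) return(out)
  ws <- window_loglik(codes, start_pwm)   # window starting at p
  we <- window_loglik(codes, end_pwm)
  p <- (w + 1L):(L - w + 1L)
  out[p] <- ws[p] - we[p - w]
  out
}

#' Composite score at one boundary
#'
#' Scalar convenience around [composite_scores()]: the score at the 0-based
#' boundary index `k`, comparing the start-PWM likelihood of
#' `sequence[k+1, k+13)` against the end-PWM likelihood of
#' `sequence[k-11, k+1)` (0-based half-open, width 12).
#'
#' @inheritParams composite_scores
#' @param k 0-based boundary index; requires `width - 1 <= k <= L - width - 1`.
#' @return The score, or `NA` if a window contains a non-ACGT base.
#' @export
composite_score <- function(start_pwm, end_pwm, sequence, k) {
  w <- ncol(start_pwm$freqs)
  L <- nchar(sequence)
  if (k < w - 1L || k > L - w - 1L) stop2("boundary k out of bounds")
  composite_scores(start_pwm, end_pwm, sequence)[k + 2L]
}

#' Correlation of PWM scores with coverage deltas
#'
#' Pearson correlation between the composite boundary score and the change in
#' coverage across the same boundary, after removing a Gaussian-smoothed fit
#' so only small-scale variation remains. Boundaries with an undefined score
#' are dropped pairwise.
#'
#' @param scores Vector from [composite_scores()] for one transcript.
#' @param track The raw [coverage_track()] of that transcript.
#' @param sigma Smoothing bandwidth removed before differencing (default 30).
#' @return Pearson r, or `NA` when fewer than 3 defined pairs or zero
#'   variance on either side.
#' @export
pwm_delta_correlation <- function(scores, track, sigma = 30) {
  v <- track_values(track)
  if (base::length(v) != base::length(scores))
    stop2("score and track lengths differ")
  resid <- v - gaussian_smooth(v, sigma)
  delta <- c(NA_real_, diff(resid))       # delta[p] = resid[p] - resid[p-1]
  keep <- !is.na(scores) & !is.na(delta)
  if (sum(keep) < 3L) return(NA_real_)
  safe_pearson(scores[keep], delta[keep])
}

shuffle_pwm <- function(pwm, perm) {
  end_pwm(pwm$freqs[, perm, drop = FALSE], side = pwm$side,
          n_fragments = pwm$n_fragments, pseudocount = pwm$pseudocount)
}

#' Permutation test for fragment-end sequence preference
#'
#' Tests, per gene, whether the observed correlation between composite PWM
#' scores and coverage deltas exceeds what position-scrambled PWMs produce.
#' Each permutation shuffles the position columns of the start and end PWMs
#' independently (column contents intact) and recomputes every gene's
#' correlation against the same shuffled pair, so the null preserves the
#' base-composition and autocorrelation structure of coverage. One-sided
#' add-one p-values: `p = (1 + #{perm r >= observed r}) / (1 + n_perm)`;
#' an undefined observed correlation gives p = 1.
#'
#' @param start_pwm,end_pwm Observed [end_pwm()] pair.
#' @param sequences Transcript sequences (see [build_pwms()]).
#' @param tracks Named list of raw [coverage_track()]s, names matching
#'   `sequences`.
#' @param n_perm Number of permutations (default 100).
#' @param sigma Smoothing bandwidth for the delta correlation.
#' @param seed Integer seed for the permutation RNG.
#' @return Data frame with one row per gene: `gene`, `r_obs`, `p`.
#' @export
permutation_test <- function(start_pwm, end_pwm, sequences, tracks,
                             n_perm = 100, sigma = 30, seed = 1) {
  stopifnot(is_count(n_perm), n_perm >= 1)
  sequences <- as_sequence_set(sequences)
  genes <- names(tracks)
  if (is.null(genes)) stop2("`tracks` must be a named list")
  w <- ncol(start_pwm$freqs)

  # precompute per-gene base codes and residual deltas once
  codes <- lapply(genes, function(g) base_codes(sequences[[g]]))
  deltas <- lapply(genes, function(g) {
    v <- track_values(tracks[[g]])
    resid <- v - gaussian_smooth(v, sigma)
    c(NA_real_, diff(resid))
  })

  gene_r <- function(sp, ep) {
    vapply(seq_along(genes), function(i) {
      b <- codes[[i]]
      L <- base::length(b)
      if (L < 2L * w) return(NA_real_)
      ws <- window_loglik(b, sp)
      we <- window_loglik(b, ep)
      p <- (w + 1L):(L - w + 1L)
      sc <- rep(NA_real_, L)
      sc[p] <- ws[p] - we[p - w]
      d <- deltas[[i]]
      keep <- !is.na(sc) & !is.na(d)
      if (sum(keep) < 3L) return(NA_real_)
      safe_pearson(sc[keep], d[keep])
    }, numeric(1))
  }

  r_obs <- gene_r(start_pwm, end_pwm)
  ge_counts <- integer(base::length(genes))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    sp <- shuffle_pwm(start_pwm, sample.int(w))
    ep <- shuffle_pwm(end_pwm, sample.int(w))
    r_perm <- gene_r(sp, ep)
    ge <- !is.na(r_perm) & !is.na(r_obs) & r_perm >= r_obs
    ge_counts <- ge_counts + as.integer(ge)
  }
  p <- (1 + ge_counts) / (1 + n_perm)
  p[is.na(r_obs)] <- 1
  data.frame(gene = genes, r_obs = r_obs, p = p)
}

#' Read/write a PWM as position-frequency TSV
#'
#' Rows are positions 1..width, columns A, C, G, T.
#'
#' @param pwm An [end_pwm()].
#' @param path TSV path.
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(t(pwm$freqs))
  df <- cbind(position = seq_len(nrow(df)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @param side Which side the stored PWM models.
#' @export
read_pwm <- function(path, side = "fragment_start") {
  df <- read.delim(path)
  end_pwm(t(as.matrix(df[, BASES])), side = side, pseudocount = NA_real_)
}
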