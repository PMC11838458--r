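#' Extract probe sequences from classified regions
#'
#' Draws fixed-width windows uniformly at random from the low- (valley) and
#' high- (peak) coverage intervals of [classify_regions()], as synthetic
#' 'reads' whose mapping uniqueness can then be assessed. Intervals shorter
#' than `width` are skipped; probes may overlap. Deterministic under `seed`.
#'
#' @param regions List with `low` and `high` interval matrices (0-based
#'   half-open), per [classify_regions()].
#' @param sequence The transcript sequence (character scalar).
#' @param width Probe width in bases (default 100).
#' @param n_per_region Probes drawn per eligible interval (default 1).
#' @param seed Integer seed.
#' @return Data frame `origin` (`"peak"` for high, `"valley"` for low),
#'   `start` (0-based), `probe` (sequence). Empty with a warning when no
#'   interval is eligible.
#' @export
extract_probes <- function(regions, sequence, width = 100, n_per_region = 1,
                           seed = 1) {
  sequence <- toupper(sequence)
  set.seed(seed)
  draw <- function(iv, origin) {
    if (is.null(iv) || nrow(iv) == 0L) return(NULL)
    rows <- lapply(seq_len(nrow(iv)), function(i) {
      lo <- iv[i, 1L]; hi <- iv[i, 2L]
      if (hi - lo < width) return(NULL)
      starts <- lo + floor(runif(n_per_region) * (hi - lo - width + 1))
      data.frame(origin = origin, start = starts,
                 probe = substring(sequence, starts + 1, starts + width))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (base::length(rows)) do.call(rbind, rows) else NULL
  }
  out <- rbind(draw(regions$high, "peak"), draw(regions$low, "valley"))
  if (is.null(out) || nrow(out) == 0L) {
    warning("no interval of at least `width` bases; no probes extracted")
    return(data.frame(origin = character(0), start = integer(0),
                      probe = character(0)))
  }
  rownames(out) <- NULL
  out
}

#' Count exact placements of a probe in a reference
#'
#' Number of distinct (sequence, offset) positions at which the probe or its
#' reverse complement occurs exactly in the reference set. A palindromic
#' probe matching at one position counts once. A probe is uniquely mapping
#' iff the count is 1. Exact full-length matching stands in for spliced
#' alignment: adequate for peak-versus-valley contingency on transcriptome
#' references.
#'
#' @param probe Character scalar over ACGT.
#' @param reference Reference sequences: named character vector,
#'   `DNAStringSet`, or FASTA path.
#' @return Integer placement count.
#' @export
count_placements <- function(probe, reference) {
  probe <- toupper(probe)
  if (grepl("[^ACGT]", probe)) stop2("probe contains non-ACGT characters")
  reference <- as_sequence_set(reference)
  subject <- Biostrings::DNAStringSet(reference)
  fwd <- sum(Biostrings::vcountPattern(probe, subject))
  rc <- revcomp_chr(probe)
  if (rc == probe) return(as.integer(fwd))  # palindrome: one strand suffices
  as.integer(fwd + sum(Biostrings::vcountPattern(rc, subject)))
}

#' Peak/valley mappability contingency table
#'
#' Assesses every probe with [count_placements()] and tallies unique
#' (count == 1) versus multi-mapping placements by origin.
#'
#' @param probes Data frame from [extract_probes()].
#' @param reference Reference sequence set.
#' @return List of class `Contingency2x2`: `peak_unique`, `peak_multi`,
#'   `valley_unique`, `valley_multi`.
#' @export
mappability_contingency <- function(probes, reference) {
  reference <- as_sequence_set(reference)
  counts <- vapply(probes$probe, count_placements, integer(1),
                   reference = reference, USE.NAMES = FALSE)
  unique_map <- counts == 1L
  peak <- probes$origin == "peak"
  contingency_2x2(peak_unique = sum(peak & unique_map),
                  peak_multi = sum(peak & !unique_map),
                  valley_unique = sum(!peak & unique_map),
                  valley_multi = sum(!peak & !unique_map))
}

#' @rdname mappability_contingency
#' @param peak_unique,peak_multi,valley_unique,valley_multi Non-negative
#'   counts.
#' @export
contingency_2x2 <- function(peak_unique, peak_multi, valley_unique,
                            valley_multi) {
  counts <- c(peak_unique, peak_multi, valley_unique, valley_multi)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop2("counts must be non-negative integers")
  structure(list(peak_unique = peak_unique, peak_multi = peak_multi,
                 valley_unique = valley_unique, valley_multi = valley_multi),
            class = "Contingency2x2")
}

#' @export
print.Contingency2x2 <- function(x, ...) {
  cat(sprintf("<Contingency2x2> peak %d/%d unique, valley %d/%d unique\n",
              x$peak_unique, x$peak_unique + x$peak_multi,
              x$valley_unique, x$valley_unique + x$valley_multi))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test by direct hypergeometric enumeration: conditioning on
#' the margins, the p-value sums the probabilities of all tables whose
#' probability does not exceed that of the observed table (with a 1e-7
#' relative slack for floating-point ties -- the standard
#' probability-ordering convention). The odds ratio is the sample odds ratio
#' `(a d)/(b c)`, reported as `Inf` when `b c = 0`.
#'
#' One-sided alternatives are the hypergeometric tail probabilities:
#' `"greater"` tests for an excess of the top-left cell (peak probes more
#' often unique than valley probes), which is the convention under which the
#' reference analysis of the 805/834 vs 493/525 table yields p = 0.017.
#'
#' @param x A [contingency_2x2()], or a 2x2 matrix / length-4 vector ordered
#'   `a, b, c, d` for the table `rbind(c(a, b), c(c, d))`.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(x, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (inherits(x, "Contingency2x2")) {
    tab <- c(x$peak_unique, x$peak_multi, x$valley_unique, x$valley_multi)
  } else if (is.matrix(x)) {
    tab <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  } else {
    tab <- as.numeric(x)
  }
  if (base::length(tab) != 4L) stop2("need a 2x2 table")
  if (any(tab < 0)) stop2("negative count in contingency table")
  a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0) stop2("empty table")
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[support >= a]),
              less = sum(probs[support <= a]))
  odds <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = odds, p_value = min(1, p))
}
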