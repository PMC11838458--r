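#' Collapse PCR duplicates by exact (start, end, UMI) key
#'
#' Raw sequenced fragment copies sharing transcript, start, end and UMI are
#' collapsed to one deduplicated record whose `dup_group_size` is the number
#' of copies observed. Exact-key collapse (no UMI edit-distance network) is
#' used: the synthetic generator emits error-free UMIs, so directional
#' clustering of near-miss UMIs would never fire. Idempotent.
#'
#' @param fragments Data frame of raw fragment copies with columns
#'   `transcript_id`, `start`, `end`, `umi` (other columns are carried
#'   through from the first copy of each group).
#' @return Deduplicated data frame with a `dup_group_size` column.
#' @export
dedup_fragments <- function(fragments) {
  if (nrow(fragments) == 0L) {
    fragments$dup_group_size <- integer(0)
    return(fragments)
  }
  if (is.null(fragments$umi)) stop2("`umi` column required for deduplication")
  key <- paste(fragments$transcript_id, fragments$start, fragments$end,
               fragments$umi, sep = "\r")
  first <- !duplicated(key)
  out <- fragments[first, , drop = FALSE]
  sizes <- table(key)
  out$dup_group_size <- as.integer(sizes[key[first]])
  rownames(out) <- NULL
  out
}

#' Positional PCR duplicate rate
#'
#' At each transcript position, among deduplicated fragments overlapping it,
#' the fraction that had at least one PCR duplicate (dup_group_size >= 2).
#' Positions covered by no fragment are undefined (`NA`). High rates flag
#' regions whose fragments amplified efficiently.
#'
#' @param fragments Deduplicated fragment data frame (one transcript) with
#'   `start`, `end`, `dup_group_size`.
#' @param length Transcript length.
#' @param transcript_id Optional identifier.
#' @return A `DupeRateTrack`: list with `transcript_id` and `rate` (numeric
#'   vector in \[0,1\] with `NA` where undefined).
#' @export
positional_dupe_rate <- function(fragments, length, transcript_id = NULL) {
  if (is.null(fragments) || nrow(fragments) == 0L) {
    return(structure(list(transcript_id = transcript_id %||% NA_character_,
                          rate = rep(NA_real_, length)),
                     class = "DupeRateTrack"))
  }
  if (is.null(fragments$dup_group_size)) stop2("`dup_group_size` column required")
  all_cov <- track_values(fragment_coverage(fragments, length, transcript_id))
  dup <- fragments[fragments$dup_group_size >= 2L, , drop = FALSE]
  dup_cov <- track_values(fragment_coverage(dup, length, transcript_id))
  rate <- ifelse(all_cov > 0, dup_cov / all_cov, NA_real_)
  structure(list(transcript_id = transcript_id %||%
                   (if (nrow(fragments)) fragments$transcript_id[1] else NA_character_),
                 rate = rate),
            class = "DupeRateTrack")
}

#' @export
print.DupeRateTrack <- function(x, ...) {
  cat(sprintf("<DupeRateTrack> %s, length %d, defined %d\n",
              x$transcript_id, base::length(x$rate), sum(!is.na(x$rate))))
  invisible(x)
}

#' PCR duplicate rate by GC bin
#'
#' Bins deduplicated fragments by the GC content of their first read into
#' 5%-wide bins \[0,0.05), ..., \[0.95,1\] (the last bin closed on both ends)
#' and reports, per bin, the fraction of fragments with at least one
#' duplicate. GC-dependent PCR amplification efficiency shows up as a trend
#' of rate across bins.
#'
#' @param fragments Deduplicated fragment data frame with `read1_gc` and
#'   `dup_group_size`.
#' @param bin_width Bin width on the GC fraction scale (default 0.05).
#' @return Data frame `bin_lo`, `bin_hi`, `n`, `rate` (rate `NA` for empty
#'   bins).
#' @export
gc_binned_dupe_rate <- function(fragments, bin_width = 0.05) {
  nb <- as.integer(round(1 / bin_width))
  lo <- round((seq_len(nb) - 1L) * bin_width, 10)
  hi <- round(lo + bin_width, 10)
  gc <- fragments$read1_gc
  if (is.null(gc)) stop2("`read1_gc` column required")
  idx <- pmin(nb, floor(gc / bin_width) + 1L)  # final bin closed on both ends
  n <- tabulate(idx, nbins = nb)
  dup <- tabulate(idx[fragments$dup_group_size >= 2L], nbins = nb)
  data.frame(bin_lo = lo, bin_hi = hi, n = n,
             rate = ifelse(n > 0, dup / n, NA_real_))
}

# Linearly interpolate NA gaps of a vector (flat extrapolation at the ends);
# all-NA input is returned as is.
interpolate_na <- function(x) {
  ok <- which(!is.na(x))
  if (base::length(ok) == 0L || base::length(ok) == base::length(x)) return(x)
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Association between PCR duplicate rate and coverage
#'
#' Do duplicate rate and coverage move together along the transcript? Both
#' tracks are Gaussian-smoothed, adjacent differences are taken, and their
#' Spearman correlation is computed over positions where the duplicate rate
#' was originally defined. Undefined duplicate-rate gaps are linearly
#' interpolated before smoothing (Gaussian smoothing needs contiguous input)
#' and re-masked afterwards. Across a gene set, the per-gene correlations are
#' tested against zero with a two-sided one-sample Wilcoxon signed-rank test
#' via [dupe_association_test()].
#'
#' @param track Raw deduplicated [coverage_track()].
#' @param dupes Matching `DupeRateTrack` from [positional_dupe_rate()].
#' @param sigma Smoothing bandwidth (default 30).
#' @param smooth_dupes Smooth the duplicate-rate track too (default `TRUE`);
#'   set `FALSE` to difference the raw rate track instead.
#' @return Spearman rho, or `NA` with fewer than 10 usable positions or zero
#'   variance.
#' @export
dupe_coverage_association <- function(track, dupes, sigma = 30,
                                      smooth_dupes = TRUE) {
  v <- track_values(track)
  rate <- dupes$rate
  if (base::length(v) != base::length(rate)) stop2("track lengths differ")
  defined <- !is.na(rate)
  if (sum(defined) < 10L) return(NA_real_)
  sv <- gaussian_smooth(v, sigma)
  sr <- interpolate_na(rate)
  if (smooth_dupes) sr <- gaussian_smooth(sr, sigma)
  sr[!defined] <- NA_real_
  dv <- diff(sv)
  dr <- diff(sr)
  keep <- !is.na(dr)
  if (sum(keep) < 10L) return(NA_real_)
  x <- dv[keep]; y <- dr[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0 ||
      base::length(unique(y)) < 2L || base::length(unique(x)) < 2L)
    return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Gene-set test of the duplicate-rate/coverage association
#'
#' Two-sided one-sample Wilcoxon signed-rank test of per-gene Spearman
#' correlations (from [dupe_coverage_association()]) against zero.
#'
#' @param rhos Numeric vector of per-gene correlations (`NA`s dropped).
#' @return List with `statistic`, `p_value`, `n`, `median_rho`.
#' @export
dupe_association_test <- function(rhos) {
  rhos <- rhos[!is.na(rhos)]
  if (base::length(rhos) < 1L) stop2("no defined correlations")
  wt <- stats::wilcox.test(rhos, mu = 0, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = base::length(rhos), median_rho = stats::median(rhos))
}
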