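#' Coverage tracks
#'
#' A `CoverageTrack` holds one per-base signal over a transcript, always in
#' transcript orientation (position 1 of `values` is the 5' end). Fragment
#' coordinates throughout the package are 0-based half-open, so a fragment
#' `[start, end)` covers `values[(start + 1):end]`.
#'
#' @param values Non-negative numeric vector, one entry per transcript base.
#' @param transcript_id Transcript identifier.
#' @param n_fragments Number of fragments the track was built from.
#' @param variant One of `"raw"`, `"smoothed"`, `"normalized"`, `"residual"`,
#'   `"corrected"`. Residual tracks may be negative.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(values, transcript_id = NA_character_,
                           n_fragments = NA_integer_, variant = "raw") {
  variant <- match.arg(variant,
                       c("raw", "smoothed", "normalized", "residual", "corrected"))
  if (!is.numeric(values)) stop2("`values` must be numeric")
  structure(
    list(transcript_id = transcript_id,
         values = as.numeric(values),
         n_fragments = n_fragments,
         variant = variant),
    class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("<CoverageTrack %s> %s, length %d, n_fragments %s\n",
              x$variant, x$transcript_id, length(x$values),
              format(x$n_fragments)))
  invisible(x)
}

#' @export
length.CoverageTrack <- function(x) length(x$values)

track_values <- function(x) {
  if (inherits(x, "CoverageTrack")) x$values else as.numeric(x)
}

#' Per-base fragment coverage
#'
#' Counts, at every transcript position, the number of fragments spanning it.
#' The whole fragment extent contributes, including the unsequenced insert
#' between the two mates: paired-end fragments in transcript space have no
#' junctions, so the region between the outer ends of the pair is covered.
#'
#' @param fragments Data frame with 0-based half-open `start`/`end` columns
#'   (the fragment-table dialect of [read_fragments()]); all rows must belong
#'   to one transcript. When UMIs are available the input should already be
#'   deduplicated (see [dedup_fragments()]).
#' @param length Transcript length in bases.
#' @param transcript_id Optional identifier; defaults to the one in
#'   `fragments` when unique.
#' @return A raw [coverage_track()]. Its values sum to the summed fragment
#'   lengths.
#' @export
fragment_coverage <- function(fragments, length, transcript_id = NULL) {
  stopifnot(is_count(length), length >= 1)
  if (is.null(fragments) || nrow(fragments) == 0L) {
    return(coverage_track(numeric(length),
                          transcript_id = transcript_id %||% NA_character_,
                          n_fragments = 0L, variant = "raw"))
  }
  st <- fragments$start
  en <- fragments$end
  if (is.null(st) || is.null(en)) stop2("`fragments` needs `start` and `end` columns")
  bad <- which(!(st >= 0 & en <= length & st < en))
  if (base::length(bad) > 0L) {
    stop2(sprintf("fragment out of bounds at row %d: [%s, %s) on length %d",
                  bad[1], format(st[bad[1]]), format(en[bad[1]]), length))
  }
  if (is.null(transcript_id)) {
    ids <- unique(fragments$transcript_id)
    transcript_id <- if (base::length(ids) == 1L) ids else NA_character_
  }
  # difference-array accumulation: O(n + L)
  delta <- numeric(length + 1L)
  inc <- tabulate(st + 1L, nbins = length)
  dec <- tabulate(en + 1L, nbins = length + 1L)
  delta[seq_len(length)] <- inc
  delta <- delta - dec
  coverage_track(cumsum(delta)[seq_len(length)],
                 transcript_id = transcript_id,
                 n_fragments = nrow(fragments), variant = "raw")
}

# Gaussian smoothing of a numeric vector; kernel truncated at +/- 4 sigma and
# renormalized over the in-bounds support at the track edges, so constant
# input maps to identical constant output (no artificial edge valleys).
gaussian_smooth <- function(x, sigma) {
  n <- base::length(x)
  if (sigma == 0 || n < 2L) return(x)
  h <- as.integer(ceiling(4 * sigma))
  k <- dnorm(seq.int(-h, h), sd = sigma)
  k <- k / sum(k)
  # convolve the mean-centered signal so constants are preserved exactly
  # (FFT round-off would otherwise leave ~1e-15 residual wiggle)
  m <- mean(x)
  xp <- c(numeric(h), x - m, numeric(h))
  wp <- c(numeric(h), rep(1, n), numeric(h))
  num <- stats::convolve(xp, k, type = "filter")
  den <- stats::convolve(wp, k, type = "filter")
  m + num / den
}

#' Gaussian smoothing of a coverage track
#'
#' Discrete Gaussian convolution with the kernel truncated at \eqn{\pm 4
#' \sigma} (mass lost < 1e-4). At the track boundaries the truncated kernel is
#' renormalized over the in-bounds positions rather than reflected or
#' zero-padded, which preserves constants exactly and avoids artificial
#' valleys at the transcript ends.
#'
#' @param track A [coverage_track()] or numeric vector.
#' @param sigma Kernel standard deviation in bases (default 30); `sigma = 0`
#'   returns the values unchanged.
#' @return A smoothed `CoverageTrack`.
#' @export
smooth_track <- function(track, sigma = 30) {
  if (sigma < 0) stop2("`sigma` must be >= 0")
  v <- track_values(track)
  tid <- if (inherits(track, "CoverageTrack")) track$transcript_id else NA_character_
  nf <- if (inherits(track, "CoverageTrack")) track$n_fragments else NA_integer_
  if (base::length(v) < 2L) {
    warning("track shorter than 2 bases returned unchanged")
    return(coverage_track(v, tid, nf, variant = "smoothed"))
  }
  coverage_track(gaussian_smooth(v, sigma), tid, nf, variant = "smoothed")
}

#' Max-normalize a coverage track to [0, 1]
#'
#' Divides by the track maximum so each gene and sample is individually scaled
#' to the 0--1 range. An all-zero track is returned unchanged with attribute
#' `all_zero = TRUE`.
#'
#' @inheritParams smooth_track
#' @return A normalized `CoverageTrack`.
#' @export
normalize_track <- function(track) {
  v <- track_values(track)
  tid <- if (inherits(track, "CoverageTrack")) track$transcript_id else NA_character_
  nf <- if (inherits(track, "CoverageTrack")) track$n_fragments else NA_integer_
  m <- max(v)
  if (m == 0) {
    out <- coverage_track(v, tid, nf, variant = "normalized")
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  out <- coverage_track(v / m, tid, nf, variant = "normalized")
  attr(out, "all_zero") <- FALSE
  out
}

#' Small-scale residual of a coverage track
#'
#' Removes the large-scale trend by subtracting the Gaussian-smoothed track
#' from the raw track, leaving the base-to-base "wiggles".
#' `residual + smoothed = raw` exactly.
#'
#' @inheritParams smooth_track
#' @return A residual `CoverageTrack` (may be negative).
#' @export
residual_track <- function(track, sigma = 30) {
  v <- track_values(track)
  sm <- track_values(smooth_track(track, sigma))
  tid <- if (inherits(track, "CoverageTrack")) track$transcript_id else NA_character_
  nf <- if (inherits(track, "CoverageTrack")) track$n_fragments else NA_integer_
  coverage_track(v - sm, tid, nf, variant = "residual")
}

# Depth-normalize one track (divide by its own mean) for cross-sample
# comparison; all-zero tracks pass through.
depth_normalize <- function(v) {
  m <- mean(v)
  if (m == 0) v else v / m
}

as_track_list <- function(x) {
  if (inherits(x, "CoverageTrack") || is.numeric(x)) list(x) else x
}

#' Replicate concordance of coverage
#'
#' Pearson correlation between the coverage of two samples over a shared gene
#' set, after normalizing for read depth by dividing each gene's track by its
#' own mean. With `method = "concatenate"` (default) the depth-normalized
#' tracks are concatenated across genes and one correlation is returned; with
#' `method = "average"` per-gene correlations are averaged.
#'
#' @param a,b Matching [coverage_track()] objects, numeric vectors, or lists
#'   of them (one per gene, in the same order).
#' @param method `"concatenate"` or `"average"`.
#' @return Pearson r, or `NA` (the undefined marker) when either side has
#'   zero variance.
#' @export
pairwise_correlation <- function(a, b, method = c("concatenate", "average")) {
  method <- match.arg(method)
  la <- as_track_list(a); lb <- as_track_list(b)
  if (base::length(la) != base::length(lb)) stop2("gene lists differ in length")
  va <- lapply(la, function(t) depth_normalize(track_values(t)))
  vb <- lapply(lb, function(t) depth_normalize(track_values(t)))
  for (i in seq_along(va)) {
    if (base::length(va[[i]]) != base::length(vb[[i]]))
      stop2("track length mismatch in gene ", i)
  }
  if (method == "concatenate") {
    return(safe_pearson(unlist(va), unlist(vb)))
  }
  rs <- mapply(safe_pearson, va, vb)
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}

safe_pearson <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (base::length(x) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Concordance of small-scale coverage variations
#'
#' Correlates the depth-normalized residual tracks (raw minus Gaussian-smoothed,
#' each gene divided by its mean raw coverage) of two samples, isolating
#' agreement of the base-scale wiggles from agreement of the broad profile.
#'
#' @inheritParams pairwise_correlation
#' @param sigma Smoothing bandwidth used to remove the large-scale trend.
#' @return Pearson r of the residuals, or `NA` when a residual has zero
#'   variance.
#' @export
local_correlation <- function(a, b, sigma = 30,
                              method = c("concatenate", "average")) {
  method <- match.arg(method)
  resid_norm <- function(t) {
    v <- depth_normalize(track_values(t))
    v - gaussian_smooth(v, sigma)
  }
  la <- lapply(as_track_list(a), resid_norm)
  lb <- lapply(as_track_list(b), resid_norm)
  if (base::length(la) != base::length(lb)) stop2("gene lists differ in length")
  if (method == "concatenate") return(safe_pearson(unlist(la), unlist(lb)))
  rs <- mapply(safe_pearson, la, lb)
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}
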