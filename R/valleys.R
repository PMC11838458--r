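# Locate local maxima of a numeric vector. Plateaus contribute their leftmost
# index; the track endpoints are eligible as boundary maxima so that valleys
# adjacent to the transcript ends remain visible. Returns 1-based indices.
local_maxima <- function(v) {
  n <- base::length(v)
  if (n == 0L) return(integer(0))
  r <- rle(v)
  k <- base::length(r$lengths)
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_max <- logical(k)
  for (i in seq_len(k)) {
    up_left <- i == 1L || r$values[i] > r$values[i - 1L]
    up_right <- i == k || r$values[i] > r$values[i + 1L]
    is_max[i] <- up_left && up_right
  }
  starts[is_max]
}

#' Detect coverage valleys on a smoothed track
#'
#' A valley is a local minimum lying between two adjacent local maxima of the
#' smoothed coverage, kept only when the drop from the minimum to *both*
#' bounding maxima is at least 10% of the gene's average (smoothed) coverage.
#' Track endpoints count as candidate bounding maxima and plateau extrema take
#' their leftmost position, so detection is deterministic.
#'
#' @param smoothed A smoothed [coverage_track()] (or numeric vector treated as
#'   already smoothed).
#' @param min_drop_frac Drop threshold as a fraction of mean coverage
#'   (default 0.1).
#' @return Data frame with one row per valley: 0-based positions `left_max`,
#'   `min_pos`, `right_max`, the drops to each side, and `water`, the local
#'   valley score from [local_valley_score()].
#' @export
find_valleys <- function(smoothed, min_drop_frac = 0.1) {
  v <- track_values(smoothed)
  empty <- data.frame(left_max = integer(0), min_pos = integer(0),
                      right_max = integer(0), left_drop = numeric(0),
                      right_drop = numeric(0), water = numeric(0))
  if (base::length(v) == 0L || all(v == 0)) return(empty)
  maxima <- local_maxima(v)
  if (base::length(maxima) < 2L) return(empty)
  thr <- min_drop_frac * mean(v)
  rows <- vector("list", base::length(maxima) - 1L)
  for (j in seq_len(base::length(maxima) - 1L)) {
    l <- maxima[j]; r <- maxima[j + 1L]
    seg <- v[(l + 1L):(r - 1L)]
    if (base::length(seg) == 0L) next
    m_rel <- which.min(seg)          # leftmost minimum for determinism
    m <- l + m_rel
    left_drop <- v[l] - v[m]
    right_drop <- v[r] - v[m]
    if (left_drop >= thr && right_drop >= thr) {
      rows[[j]] <- data.frame(left_max = l - 1L, min_pos = m - 1L,
                              right_max = r - 1L,
                              left_drop = left_drop, right_drop = right_drop)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (base::length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$water <- vapply(seq_len(nrow(out)), function(i)
    water_volume(v, out$left_max[i], out$right_max[i]), numeric(1))
  rownames(out) <- NULL
  out
}

# Water held between two bounding maxima (0-based positions) of track v:
# sum over strictly interior bases of max(0, min(left, right) - cov).
water_volume <- function(v, left_max, right_max) {
  lvl <- min(v[left_max + 1L], v[right_max + 1L])
  inter <- v[(left_max + 2L):right_max]
  sum(pmax(0, lvl - inter))
}

#' Local valley score ("water")
#'
#' The amount of water one valley could hold: for every base strictly between
#' the bounding maxima, the height of min(left peak, right peak) above the
#' coverage at that base, summed. Numerically negative terms are clamped to
#' zero.
#'
#' @param valley One row of the data frame from [find_valleys()] (or any list
#'   with `left_max` and `right_max`).
#' @param smoothed The smoothed track the valley was detected on.
#' @return Non-negative water volume.
#' @export
local_valley_score <- function(valley, smoothed) {
  v <- track_values(smoothed)
  water_volume(v, valley$left_max[1], valley$right_max[1])
}

#' Global valley score
#'
#' The package's summary statistic for coverage non-uniformity: smooth the
#' track, detect valleys, and total the water all of them could hold,
#' normalized by mean smoothed coverage times transcript length. The score is
#' invariant under scaling the coverage by any positive constant; larger
#' values mean less uniform coverage; constant or all-zero coverage scores 0.
#'
#' @param track A raw (or 3'-bias corrected) [coverage_track()] or numeric
#'   vector.
#' @param sigma Gaussian smoothing bandwidth in bases (default 30); `sigma =
#'   0` skips smoothing.
#' @param min_drop_frac Valley drop threshold (see [find_valleys()]).
#' @return Non-negative global valley score.
#' @export
global_valley_score <- function(track, sigma = 30, min_drop_frac = 0.1) {
  v <- track_values(track)
  if (base::length(v) == 0L || all(v == 0)) return(0)
  sm <- gaussian_smooth(v, sigma)
  vals <- find_valleys(sm, min_drop_frac = min_drop_frac)
  if (nrow(vals) == 0L) return(0)
  sum(vals$water) / (mean(sm) * base::length(sm))
}

#' Fit the exponential 3' bias of a sample against a reference
#'
#' PolyA selection of partially degraded RNA enriches coverage toward the 3'
#' end. Pooling all genes, the natural log of the ratio between the sample's
#' and a low-bias reference's coverage is regressed by OLS on the distance
#' from the 3' end (bases), the relative position along the transcript
#' (5' position / length), and their interaction, with one shared set of
#' coefficients for every gene. Positions where either track is zero are
#' excluded.
#'
#' @param sample,reference Named lists of raw [coverage_track()] objects over
#'   the same gene set (reference = a sample with limited 3' bias, e.g.
#'   unselected or highest-RIN).
#' @return A `BiasFit` list: coefficients `beta0`, `beta_d` (per base),
#'   `beta_r`, `beta_dr`, the reference identifier, and `n_points` used.
#' @export
fit_3prime_bias <- function(sample, reference, reference_id = "reference") {
  genes <- names(sample) %||% seq_along(sample)
  if (base::length(sample) != base::length(reference))
    stop2("sample and reference gene sets differ")
  ys <- list(); ds <- list(); rs <- list()
  for (i in seq_along(sample)) {
    vs <- track_values(sample[[i]])
    vr <- track_values(reference[[i]])
    if (base::length(vs) != base::length(vr))
      stop2("track length mismatch for gene ", genes[i])
    L <- base::length(vs)
    keep <- vs > 0 & vr > 0
    if (!any(keep)) next
    pos <- which(keep) - 1L                    # 0-based 5' position
    ys[[i]] <- log(vs[keep] / vr[keep])
    ds[[i]] <- (L - 1L) - pos                  # distance from 3' end
    rs[[i]] <- pos / L                         # relative position
  }
  y <- unlist(ys); d <- unlist(ds); r <- unlist(rs)
  if (base::length(y) < 10L) stop2("fewer than 10 usable positions")
  if (stats::sd(d) == 0 || stats::sd(r) == 0)
    stop2("zero-variance predictor in 3' bias fit")
  fit <- stats::lm(y ~ d + r + d:r)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop2("collinear 3' bias design (aliased coefficient); ",
          "supply genes of varying lengths")
  }
  structure(list(beta0 = unname(cf["(Intercept)"]),
                 beta_d = unname(cf["d"]),
                 beta_r = unname(cf["r"]),
                 beta_dr = unname(cf["d:r"]),
                 reference_id = reference_id,
                 n_points = base::length(y)),
            class = "BiasFit")
}

#' @export
print.BiasFit <- function(x, ...) {
  cat(sprintf(
    "<BiasFit vs %s> beta0 %.4g, beta_d %.4g /base, beta_r %.4g, beta_dr %.4g (n = %d)\n",
    x$reference_id, x$beta0, x$beta_d, x$beta_r, x$beta_dr, x$n_points))
  invisible(x)
}

#' Remove fitted 3' bias from a coverage track
#'
#' Divides the coverage elementwise by the fitted positional factor
#' `exp(beta0 + beta_d d + beta_r r + beta_dr d r)`, flattening the
#' exponential 3' trend while preserving positivity. Global valley scores of
#' polyA or degraded samples should be computed on this corrected coverage.
#'
#' @param track A raw [coverage_track()].
#' @param fit A `BiasFit` from [fit_3prime_bias()] on the same sample.
#' @return A corrected `CoverageTrack`.
#' @export
correct_3prime_bias <- function(track, fit) {
  v <- track_values(track)
  L <- base::length(v)
  pos <- seq_len(L) - 1L
  d <- (L - 1L) - pos
  r <- pos / L
  factor <- exp(fit$beta0 + fit$beta_d * d + fit$beta_r * r + fit$beta_dr * d * r)
  tid <- if (inherits(track, "CoverageTrack")) track$transcript_id else NA_character_
  nf <- if (inherits(track, "CoverageTrack")) track$n_fragments else NA_integer_
  coverage_track(v / factor, tid, nf, variant = "corrected")
}

# Collapse a sorted 0-based position set into maximal disjoint half-open
# intervals, returned as a two-column matrix.
positions_to_intervals <- function(pos) {
  if (base::length(pos) == 0L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  pos <- sort(unique(pos))
  brk <- which(diff(pos) > 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, base::length(pos))] + 1L
  cbind(start = starts, end = ends)
}

#' Classify low- and high-coverage regions
#'
#' Splits the smoothed track's value range per gene into thirds. Low regions
#' are the portions of detected valleys whose smoothed coverage is in the
#' bottom third; high regions are neighborhoods (within `peak_halfwidth`
#' bases) of the valleys' bounding maxima whose coverage is in the top third.
#' The two classes never overlap because their cutoffs are disjoint.
#'
#' @param smoothed Smoothed [coverage_track()] or numeric vector.
#' @param valleys Data frame from [find_valleys()] on the same track.
#' @param peak_halfwidth Half-width (bases) of the neighborhood around a
#'   bounding maximum (default 50).
#' @return List of two matrices of 0-based half-open intervals: `low` and
#'   `high`.
#' @export
classify_regions <- function(smoothed, valleys, peak_halfwidth = 50) {
  v <- track_values(smoothed)
  L <- base::length(v)
  emptym <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  rng <- range(v)
  if (diff(rng) == 0 || nrow(valleys) == 0L)
    return(list(low = emptym, high = emptym))
  low_cut <- rng[1] + diff(rng) / 3
  high_cut <- rng[1] + 2 * diff(rng) / 3

  low_pos <- integer(0)
  high_pos <- integer(0)
  for (i in seq_len(nrow(valleys))) {
    span <- (valleys$left_max[i] + 1L):(valleys$right_max[i] - 1L)
    low_pos <- c(low_pos, span[v[span + 1L] <= low_cut])
    for (p in c(valleys$left_max[i], valleys$right_max[i])) {
      nb <- max(0L, p - peak_halfwidth):min(L - 1L, p + peak_halfwidth)
      high_pos <- c(high_pos, nb[v[nb + 1L] >= high_cut])
    }
  }
  list(low = positions_to_intervals(low_pos),
       high = positions_to_intervals(high_pos))
}

#' Write valley tables
#'
#' One row per valley with its gene, bounding positions, water, and the
#' gene's global valley score.
#'
#' @param valley_list Named list (by gene) of [find_valleys()] data frames.
#' @param gvs Named numeric vector of global valley scores.
#' @param path Output TSV path.
#' @export
write_valley_table <- function(valley_list, gvs, path) {
  rows <- lapply(names(valley_list), function(g) {
    df <- valley_list[[g]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(gene = g, left = df$left_max, min = df$min_pos,
               right = df$right_max, water = df$water,
               gvs = unname(gvs[g]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (base::length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), left = integer(0), min = integer(0),
               right = integer(0), water = numeric(0), gvs = numeric(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
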