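#' One-to-All curves and local baselines
#'
#' The One-to-All (O2A) curve of an entity is the rank-order (descending)
#' plot of all predicted scores involving it from one perspective. Its local
#' baseline is the point separating the high-scoring head from the tail:
#' for dense curves (n > 100) the knee of the LOESS-smoothed curve found by
#' the Kneedle algorithm; for sparse curves (n <= 100), where a knee cannot
#' be estimated reliably, the median of the score distribution.
#'
#' @name o2a_baseline
NULL

#' Build a One-to-All rank-order curve
#'
#' Sorts an entity's scored partners by descending score (ties broken by
#' partner id, so the curve is deterministic) and attaches percentile ranks.
#' The percentile of rank k is (k-1)/(n-1) — top partner 0, bottom partner 1
#' — with tied scores assigned the mean percentile of their tie block, so
#' curves of different sizes are comparable. A single-point curve gets
#' percentile 0.5.
#'
#' @param view data.frame with columns `partner`, `score` (as returned by
#'   [entity_view()]).
#' @param entity_id Identifier of the focal entity.
#' @param axis `"A"` or `"B"`.
#' @return An `o2a_curve`: list with `entity_id`, `axis`, `partners`,
#'   `scores` (non-increasing), `percentiles` (non-decreasing), `n`.
#' @export
build_o2a <- function(view, entity_id, axis = c("A", "B")) {
  axis <- match.arg(axis)
  if (is.null(view) || nrow(view) == 0L) {
    stop("empty view for entity ", entity_id, call. = FALSE)
  }
  ord <- order(-view$score, view$partner, method = "radix")
  scores <- view$score[ord]
  n <- length(scores)
  if (n == 1L) {
    pct <- 0.5
  } else {
    pct <- (seq_len(n) - 1) / (n - 1)
    # tied scores share the mean percentile of their block
    pct <- as.vector(tapply(pct, match(scores, unique(scores)), mean)[
      match(scores, unique(scores))])
  }
  structure(
    list(entity_id = entity_id, axis = axis,
         partners = view$partner[ord], scores = scores,
         percentiles = pct, n = n),
    class = "o2a_curve"
  )
}

#' @export
print.o2a_curve <- function(x, ...) {
  cat(sprintf("<o2a_curve> %s (axis %s), n = %d, scores [%.4g, %.4g]\n",
              x$entity_id, x$axis, x$n, x$scores[x$n], x$scores[1L]))
  invisible(x)
}

#' LOESS-smooth a dense O2A curve
#'
#' Locally weighted linear regression of score on normalized rank, evaluated
#' at every rank, output clipped to [0, 1]. Used only on dense curves before
#' knee detection, to keep score noise from creating spurious curvature
#' maxima.
#'
#' @param curve An `o2a_curve` with `n > 100`.
#' @param span Smoothing span in (0, 1]: fraction of points in each local fit.
#' @return Numeric vector of fitted values, one per rank.
#' @export
loess_smooth <- function(curve, span = 0.3) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("span must be in (0, 1]", call. = FALSE)
  }
  n <- curve$n
  x <- (seq_len(n) - 1) / (n - 1)
  fit <- stats::lowess(x, curve$scores, f = span, iter = 0L)
  pmin(pmax(fit$y, 0), 1)
}

#' Kneedle knee detection on a non-increasing curve
#'
#' Min-max normalizes x and y to the unit square, forms the difference curve
#' between the normalized curve and its chord, and returns the first local
#' maximum of the difference curve that qualifies under the
#' sensitivity-adjusted threshold of Kneedle (a candidate knee is confirmed
#' when the difference curve subsequently drops below `d[knee] - S * mean(dx)`
#' before any later local maximum takes over). The chord side is chosen
#' automatically, so knees of concave-decreasing curves and elbows of
#' convex-decreasing curves are both found. Returns `NULL` when no point
#' qualifies (e.g. a straight line, whose difference curve is identically 0).
#'
#' @param x Increasing numeric vector (e.g. ranks).
#' @param y Non-increasing numeric vector, same length, `length >= 3`.
#' @param sensitivity Kneedle sensitivity S >= 0; larger is more conservative.
#' @return `NULL`, or list with `knee_index` and `knee_y` (raw y at the knee).
#' @export
kneedle_knee <- function(x, y, sensitivity = 1.0) {
  n <- length(y)
  if (length(x) != n || n < 3L) stop("need length >= 3", call. = FALSE)
  if (any(diff(y) > 1e-12)) stop("y must be non-increasing", call. = FALSE)
  if (diff(range(y)) == 0) return(NULL)
  xn <- (x - x[1L]) / (x[n] - x[1L])
  yn <- (y - min(y)) / (max(y) - min(y))
  chord <- 1 - xn
  d <- yn - chord
  # concave-decreasing curves sit above the chord, convex-decreasing below;
  # orient the difference curve so knees are maxima either way
  if (mean(d) < 0) d <- -d
  dx_mean <- mean(diff(xn))
  is_lmx <- c(FALSE, d[2:(n - 1)] >= d[1:(n - 2)] &
                d[2:(n - 1)] >= d[3:n], FALSE)
  lmx <- which(is_lmx & d > 0)
  if (!length(lmx)) return(NULL)
  for (k in seq_along(lmx)) {
    i <- lmx[k]
    thresh <- d[i] - sensitivity * dx_mean
    stop_at <- if (k < length(lmx)) lmx[k + 1L] - 1L else n
    j <- i + 1L
    while (j <= stop_at) {
      if (d[j] < thresh) {
        return(list(knee_index = i, knee_y = y[i]))
      }
      j <- j + 1L
    }
  }
  NULL
}

oriented_chord_distance <- function(scores) {
  n <- length(scores)
  if (diff(range(scores)) == 0) return(rep(0, n))
  xn <- (seq_len(n) - 1) / (n - 1)
  yn <- (scores - min(scores)) / (max(scores) - min(scores))
  d <- yn - (1 - xn)
  if (mean(d) < 0) d <- -d
  d
}

#' Locate the local baseline of an O2A curve
#'
#' Dense curves (`n > 100`): LOESS-smooth, then Kneedle. Smoothing makes
#' knee *detection* robust to score noise but biases its *location* by up
#' to half the smoothing window (the corner's chord-distance maximum drifts
#' toward the shallower slope), so the knee index is refined to the raw
#' curve's chord-distance maximum within the smoothing window around the
#' smoothed knee, and the cutoff score is read from the raw curve there
#' (the smoothed value is a fit artifact). Sparse curves (`n <= 100`), or
#' dense curves on which Kneedle finds no knee, fall back to the score
#' median; the cutoff percentile is then that of the point whose score is
#' nearest the median (ties toward the better rank). The curve's score mean
#' and population standard deviation are recorded for the
#' standardized-distance features.
#'
#' @param curve An `o2a_curve`.
#' @param span LOESS span for dense curves.
#' @param sensitivity Kneedle sensitivity.
#' @return A `baseline`: list with `entity_id`, `axis`, `n`, `method`
#'   (`"kneedle"` or `"median"`), `cutoff_score`, `cutoff_percentile`,
#'   `mean_score`, `sd_score`.
#' @export
locate_baseline <- function(curve, span = 0.3, sensitivity = 1.0) {
  n <- curve$n
  mean_score <- mean(curve$scores)
  sd_score <- sqrt(mean((curve$scores - mean_score)^2))
  method <- "median"
  knee <- NULL
  if (n > 100L) {
    smooth <- loess_smooth(curve, span = span)
    smooth <- cummin(smooth)  # enforce monotonicity lost to fit wiggle
    knee <- kneedle_knee(seq_len(n), smooth, sensitivity = sensitivity)
    if (!is.null(knee)) method <- "kneedle"
  }
  if (method == "kneedle") {
    # refine within the smoothing window: raw chord-distance maximum
    d_raw <- oriented_chord_distance(curve$scores)
    w <- max(3L, ceiling(span * n / 2))
    lo <- max(1L, knee$knee_index - w)
    hi <- min(n, knee$knee_index + w)
    i <- lo + which.max(d_raw[lo:hi]) - 1L
    cutoff_score <- curve$scores[i]
    cutoff_percentile <- curve$percentiles[i]
  } else {
    cutoff_score <- stats::median(curve$scores)
    # nearest score to the median, ties (incl. float-level, e.g. the two
    # central scores of an even-n curve) resolved toward the better rank
    d <- abs(curve$scores - cutoff_score)
    i <- which(d <= min(d) + 1e-12)[1L]
    cutoff_percentile <- curve$percentiles[i]
  }
  structure(
    list(entity_id = curve$entity_id, axis = curve$axis, n = n,
         method = method, cutoff_score = cutoff_score,
         cutoff_percentile = cutoff_percentile,
         mean_score = mean_score, sd_score = sd_score),
    class = "rp_baseline"
  )
}

#' @export
print.rp_baseline <- function(x, ...) {
  cat(sprintf(
    "<baseline> %s (axis %s, n=%d): %s cutoff %.4f at percentile %.4f\n",
    x$entity_id, x$axis, x$n, x$method, x$cutoff_score, x$cutoff_percentile))
  invisible(x)
}

#' Curves and baselines for every entity of a score table
#'
#' @param table A `score_table`.
#' @param span,sensitivity Passed to [locate_baseline()].
#' @return List with `curves_a`, `curves_b`, `baselines_a`, `baselines_b`,
#'   each a named list keyed by entity id.
#' @export
compute_baselines <- function(table, span = 0.3, sensitivity = 1.0) {
  one_axis <- function(axis) {
    ids <- names(if (axis == "A") table$index_a else table$index_b)
    curves <- lapply(ids, function(id) {
      build_o2a(entity_view(table, axis, id), id, axis)
    })
    names(curves) <- ids
    baselines <- lapply(curves, locate_baseline,
                        span = span, sensitivity = sensitivity)
    list(curves = curves, baselines = baselines)
  }
  a <- one_axis("A")
  b <- one_axis("B")
  list(curves_a = a$curves, curves_b = b$curves,
       baselines_a = a$baselines, baselines_b = b$baselines)
}

#' Baselines as a data.frame
#'
#' @param ctx Result of [compute_baselines()].
#' @return data.frame with one row per entity and axis.
#' @export
baseline_table <- function(ctx) {
  row <- function(bl) {
    data.frame(id = bl$entity_id, axis = bl$axis, n = bl$n,
               method = bl$method, cutoff_score = bl$cutoff_score,
               cutoff_percentile = bl$cutoff_percentile,
               mean = bl$mean_score, sd = bl$sd_score,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(ctx$baselines_a, row),
                          lapply(ctx$baselines_b, row)))
  rownames(out) <- NULL
  out
}
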