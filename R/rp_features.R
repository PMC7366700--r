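#' Reciprocal-perspective context features
#'
#' For a pair (X, Y) the thirteen RP features summarize where the pair sits
#' on X's One-to-All curve, on Y's, and relative to each entity's local
#' baseline. Rank-type features use percentile ranks so perspectives of
#' different sizes are comparable. Binary above-threshold indicators are
#' deliberately not computed: the raw score lets the model learn a global
#' threshold, and the fold differences carry the local-threshold signal.
#'
#' @name rp_features
NULL

RP_FEATURE_COLUMNS <- c("raw_score", "rxy", "ryx", "arro", "rxt", "sxt",
                        "ryt", "syt", "pdx", "pdy", "fdx", "fdy",
                        "stdx", "stdy")

FD_EPS <- 1e-6

curve_percentile_of <- function(curve, partner, perspective) {
  i <- match(partner, curve$partners)
  if (is.na(i)) {
    stop(sprintf("pair missing from the %s perspective (entity %s)",
                 perspective, curve$entity_id), call. = FALSE)
  }
  curve$percentiles[i]
}

#' RP feature vector for a single pair
#'
#' @param a_id,b_id The pair's entity ids (A-side, B-side).
#' @param m The pair's initial (raw) score.
#' @param curve_a,baseline_a O2A curve and baseline of the A-side entity.
#' @param curve_b,baseline_b O2A curve and baseline of the B-side entity.
#' @return Named numeric vector over the fixed feature columns:
#'   \describe{
#'     \item{raw_score}{the initial score m, passed through untransformed}
#'     \item{rxy, ryx}{percentile rank of the pair in A's and B's curve}
#'     \item{arro}{adjusted reciprocal rank order, (1-rxy)(1-ryx); 1 iff the
#'       pair is uniquely top-ranked from both perspectives}
#'     \item{rxt, sxt, ryt, syt}{cutoff percentile and score of each baseline}
#'     \item{pdx, pdy}{percentile differences rxt-rxy, ryt-ryx (positive =
#'       better than the local cutoff)}
#'     \item{fdx, fdy}{fold differences (m-sxt)/max(sxt, 1e-6) and the Y-side
#'       analogue (positive = above the local threshold)}
#'     \item{stdx, stdy}{standardized distance of m from the curve's score
#'       mean, in population-sd units (0 when the sd is 0)}
#'   }
#' @export
pair_features <- function(a_id, b_id, m, curve_a, baseline_a,
                          curve_b, baseline_b) {
  rxy <- curve_percentile_of(curve_a, b_id, "A")
  ryx <- curve_percentile_of(curve_b, a_id, "B")
  sxt <- baseline_a$cutoff_score
  syt <- baseline_b$cutoff_score
  stdx <- if (baseline_a$sd_score > 0) {
    (m - baseline_a$mean_score) / baseline_a$sd_score
  } else 0
  stdy <- if (baseline_b$sd_score > 0) {
    (m - baseline_b$mean_score) / baseline_b$sd_score
  } else 0
  c(raw_score = m,
    rxy = rxy, ryx = ryx,
    arro = (1 - rxy) * (1 - ryx),
    rxt = baseline_a$cutoff_percentile, sxt = sxt,
    ryt = baseline_b$cutoff_percentile, syt = syt,
    pdx = baseline_a$cutoff_percentile - rxy,
    pdy = baseline_b$cutoff_percentile - ryx,
    fdx = (m - sxt) / max(sxt, FD_EPS),
    fdy = (m - syt) / max(syt, FD_EPS),
    stdx = stdx, stdy = stdy)
}

#' RP feature matrix for a list of pairs
#'
#' @param table A `score_table`.
#' @param ctx Curves and baselines from [compute_baselines()].
#' @param pairs data.frame with columns `a`, `b`; every pair must be scored
#'   and every referenced entity must have a baseline.
#' @return data.frame: columns `a`, `b`, then the fixed feature columns, rows
#'   in input order.
#' @export
batch_features <- function(table, ctx, pairs) {
  if (nrow(pairs) == 0L) {
    out <- as.data.frame(c(list(a = character(), b = character()),
                           stats::setNames(rep(list(numeric()),
                                               length(RP_FEATURE_COLUMNS)),
                                           RP_FEATURE_COLUMNS)),
                         stringsAsFactors = FALSE)
    return(out)
  }
  missing_a <- setdiff(unique(pairs$a), names(ctx$baselines_a))
  missing_b <- setdiff(unique(pairs$b), names(ctx$baselines_b))
  if (length(missing_a) || length(missing_b)) {
    stop("no baseline for entity: ",
         paste(c(missing_a, missing_b), collapse = ", "), call. = FALSE)
  }
  m <- pair_scores(table, pairs$a, pairs$b)
  feats <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_features(pairs$a[i], pairs$b[i], m[i],
                  ctx$curves_a[[pairs$a[i]]], ctx$baselines_a[[pairs$a[i]]],
                  ctx$curves_b[[pairs$b[i]]], ctx$baselines_b[[pairs$b[i]]])
  }, numeric(length(RP_FEATURE_COLUMNS)))
  out <- cbind(data.frame(a = pairs$a, b = pairs$b, stringsAsFactors = FALSE),
               as.data.frame(t(feats)))
  names(out) <- c("a", "b", RP_FEATURE_COLUMNS)
  rownames(out) <- NULL
  out
}
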