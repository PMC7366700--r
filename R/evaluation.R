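#' Evaluation, re-ranking and tiering
#'
#' Bootstrap ROC/PR comparison of the refined scores against the original
#' predictor, Welch significance tests, Difference-of-Scores candidate
#' discovery, lambda-weighted combined ranking, and mirDIP-convention
#' confidence tiers.
#'
#' @name evaluation
NULL

#' ROC and PR AUC of a score vector
#'
#' ROC AUC is computed by the rank (Mann–Whitney) formula, which equals the
#' trapezoidal area over all thresholds and gives tied scores half credit.
#' PR AUC uses, by default, the step-wise precision envelope (the sum of
#' precision at each recall increment, as thresholds sweep through the
#' grouped unique scores); `pr_method = "trapezoid"` interpolates linearly
#' between PR points instead.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param y Binary labels (0/1), same length; both classes required.
#' @param pr_method `"step"` (default) or `"trapezoid"`.
#' @return List with `roc_auc` and `pr_auc`.
#' @export
roc_pr_auc <- function(scores, y, pr_method = c("step", "trapezoid")) {
  pr_method <- match.arg(pr_method)
  y <- as.integer(y)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  roc_auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # sweep thresholds over grouped unique scores, descending
  ord <- order(-scores)
  ys <- y[ord]
  ss <- scores[ord]
  grp_end <- which(diff(ss) != 0)
  grp_end <- c(grp_end, length(ss))
  tp <- cumsum(ys)[grp_end]
  fp <- grp_end - tp
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  if (pr_method == "step") {
    pr_auc <- sum(diff(c(0, recall)) * precision)
  } else {
    prev_r <- c(0, recall[-length(recall)])
    prev_p <- c(1, precision[-length(precision)])
    pr_auc <- sum((recall - prev_r) * (precision + prev_p) / 2)
  }
  list(roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Paired stratified bootstrap of ROC/PR AUC
#'
#' Resamples test rows with replacement `n_boot` times, stratified within
#' class so every resample keeps both classes, and evaluates every score
#' column on the same resample (a paired design, the stronger comparison
#' when two models are tested on one test set).
#'
#' @param score_list Named list of score vectors (e.g.
#'   `list(refined = ..., original = ...)`), all aligned with `y`.
#' @param y Binary labels.
#' @param n_boot Number of bootstrap iterations (>= 2).
#' @param seed Integer seed.
#' @param pr_method Passed to [roc_pr_auc()].
#' @return A `boot_auc` object: list with `roc` and `pr` (each a matrix,
#'   n_boot x model), `summary` data.frame of mu/sigma, `n_boot`, `seed`.
#' @export
bootstrap_auc <- function(score_list, y, n_boot = 1000L, seed = 1L,
                          pr_method = "step") {
  if (!is.list(score_list)) score_list <- list(score = score_list)
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  y <- as.integer(y)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (length(unique(score_list[[1L]])) == 1L) {
    stop("constant scores give a single ROC point", call. = FALSE)
  }
  models <- names(score_list)
  roc <- matrix(NA_real_, n_boot, length(models),
                dimnames = list(NULL, models))
  pr <- roc
  withr::with_seed(seed, {
    for (i in seq_len(n_boot)) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      for (m in models) {
        a <- roc_pr_auc(score_list[[m]][idx], y[idx], pr_method = pr_method)
        roc[i, m] <- a$roc_auc
        pr[i, m] <- a$pr_auc
      }
    }
  })
  summary <- data.frame(
    model = models,
    roc_auc_mean = colMeans(roc), roc_auc_sd = apply(roc, 2, stats::sd),
    pr_auc_mean = colMeans(pr), pr_auc_sd = apply(pr, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(roc = roc, pr = pr, summary = summary,
                 n_boot = n_boot, seed = seed),
            class = "boot_auc")
}

#' @export
print.boot_auc <- function(x, ...) {
  cat(sprintf("<boot_auc> %d iterations\n", x$n_boot))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Welch's unequal-variances t-test p-value
#'
#' Two-sided, with Welch–Satterthwaite degrees of freedom. Used to compare
#' the bootstrap AUC distributions of two models.
#'
#' @param auc_a,auc_b Numeric vectors, length >= 2, finite.
#' @return The p-value.
#' @export
welch_test <- function(auc_a, auc_b) {
  if (length(auc_a) < 2L || length(auc_b) < 2L) {
    stop("need >= 2 values per sample", call. = FALSE)
  }
  if (!all(is.finite(auc_a)) || !all(is.finite(auc_b))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(auc_a) == 0 && stats::sd(auc_b) == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  stats::t.test(auc_a, auc_b, var.equal = FALSE)$p.value
}

#' Lambda-weighted combined score
#'
#' `s = (1 - lambda) * m * lambda * r`: the original score weighted by
#' (1 - lambda) times the refined score weighted by lambda. Because the
#' weights multiply, any lambda in (0, 1) yields the same ranking as the
#' plain product m * r; the weighting rescales, it does not re-rank.
#'
#' @param m Original scores in [0, 1].
#' @param r Refined scores in [0, 1].
#' @param lambda Weight in [0, 1].
#' @param normalize Min-max normalize the result over the batch to [0, 1]?
#' @return Numeric vector of combined scores.
#' @export
combined_score <- function(m, r, lambda = 0.5, normalize = FALSE) {
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
  s <- (1 - lambda) * m * lambda * r
  if (normalize && length(s) && diff(range(s)) > 0) {
    s <- (s - min(s)) / (max(s) - min(s))
  }
  s
}

#' Candidate discovery by Difference of Scores
#'
#' Keeps the pairs with `DoS >= threshold` and returns them in two
#' complementary orders: by DoS descending (serendipitous putative false
#' negatives of the original predictor) and by refined score descending
#' (the cascade's most confident calls). Ties break by refined score, then
#' pair key.
#'
#' @param pairs data.frame with columns `a`, `b`, aligned with the scores.
#' @param refined,original Aligned numeric score vectors.
#' @param threshold Minimum DoS to keep (default 0.5).
#' @return List of data.frames `by_dos` and `by_refined`, each with columns
#'   `a`, `b`, `dos`, `refined`, `original`.
#' @export
dos_candidates <- function(pairs, refined, original, threshold = 0.5) {
  d <- dos(refined, original)
  keep <- which(d >= threshold)
  out <- data.frame(a = pairs$a[keep], b = pairs$b[keep], dos = d[keep],
                    refined = refined[keep], original = original[keep],
                    stringsAsFactors = FALSE)
  by_dos <- out[order(-out$dos, -out$refined, out$a, out$b), , drop = FALSE]
  by_refined <- out[order(-out$refined, -out$dos, out$a, out$b), ,
                    drop = FALSE]
  rownames(by_dos) <- rownames(by_refined) <- NULL
  list(by_dos = by_dos, by_refined = by_refined)
}

#' Confidence tiers on refined-score rank
#'
#' Nested cumulative tiers top-1% in top-5% in top-10% in top-33%, remainder
#' bottom-66% (the mirDIP dataset convention). Each pair is labelled with
#' its innermost tier; tier boundary counts are `ceiling(fraction * N)`.
#'
#' @param scores Numeric refined scores, length >= 1.
#' @return Factor of tier labels (`top1`, `top5`, `top10`, `top33`,
#'   `bottom66`), aligned with `scores`.
#' @export
tier_assignment <- function(scores) {
  n <- length(scores)
  if (n < 1L) stop("need at least one score", call. = FALSE)
  ranks <- rank(-scores, ties.method = "first")
  cuts <- ceiling(c(top1 = 0.01, top5 = 0.05, top10 = 0.10,
                    top33 = 0.33) * n)
  labels <- rep("bottom66", n)
  for (tier in rev(names(cuts))) labels[ranks <= cuts[[tier]]] <- tier
  factor(labels, levels = c("top1", "top5", "top10", "top33", "bottom66"))
}

#' End-to-end evaluation report
#'
#' Runs the paired bootstrap over refined and original scores on a labelled
#' test set and summarizes the comparison.
#'
#' @param refined,original Aligned score vectors on the test pairs.
#' @param y Binary labels for the test pairs.
#' @param n_boot,seed,pr_method Passed to [bootstrap_auc()].
#' @return An `eval_report`: list with the `boot_auc` object, point AUCs,
#'   and Welch p-values (`p_value_roc`, `p_value_pr`).
#' @export
evaluate_rescoring <- function(refined, original, y, n_boot = 1000L,
                               seed = 1L, pr_method = "step") {
  boot <- bootstrap_auc(list(refined = refined, original = original), y,
                        n_boot = n_boot, seed = seed, pr_method = pr_method)
  point <- list(refined = roc_pr_auc(refined, y, pr_method),
                original = roc_pr_auc(original, y, pr_method))
  structure(
    list(boot = boot, point = point,
         p_value_roc = welch_test(boot$roc[, "refined"],
                                  boot$roc[, "original"]),
         p_value_pr = welch_test(boot$pr[, "refined"],
                                 boot$pr[, "original"]),
         n_boot = n_boot, seed = seed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$boot)
  cat(sprintf("Welch p (ROC): %.3g   Welch p (PR): %.3g\n",
              x$p_value_roc, x$p_value_pr))
  invisible(x)
}
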