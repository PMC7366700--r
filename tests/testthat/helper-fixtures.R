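# Shared fixtures: all built in code at test time.

# Write a pairs data.frame to a temp TSV and load it as a score_table.
tsv_table <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(paste(df$a, df$b, formatC(df$score, digits = 17, format = "g"),
                   sep = "\t"), path)
  load_scores(path, ...)
}

# Random sparse bipartite score table.
random_table <- function(n_pairs, n_a = 8, n_b = 40, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(a = sprintf("m%02d", seq_len(n_a)),
                        b = sprintf("g%03d", seq_len(n_b)),
                        stringsAsFactors = FALSE)
    idx <- sample.int(nrow(grid), n_pairs)
    df <- grid[idx, ]
    df$score <- runif(n_pairs)
    rownames(df) <- NULL
    df
  })
}

# O2A curve straight from a named score vector.
o2a_from_scores <- function(scores, id = "e", axis = "A") {
  partners <- names(scores)
  if (is.null(partners)) partners <- sprintf("p%04d", seq_along(scores))
  build_o2a(data.frame(partner = partners, score = unname(scores),
                       stringsAsFactors = FALSE), id, axis)
}

# Noiseless two-slope descending curve with a planted knee at rank k0:
# a shallow head followed by a steep tail (randomized levels and slopes).
two_slope_curve <- function(n, k0, y_top = 0.95, y_knee = 0.75,
                            y_end = 0.05) {
  c(seq(y_top, y_knee, length.out = k0),
    seq(y_knee, y_end, length.out = n - k0 + 1)[-1])
}

# O(n^2) oracle for descending-curve percentile ranks: for each point, the
# mean over its score-tie block of (rank - 1) / (n - 1).
percentile_oracle <- function(sorted_scores) {
  n <- length(sorted_scores)
  if (n == 1) return(0.5)
  base <- (seq_len(n) - 1) / (n - 1)
  vapply(seq_len(n), function(i) {
    mean(base[which(sorted_scores == sorted_scores[i])])
  }, numeric(1))
}

# Mann-Whitney oracle for ROC AUC: concordant-pair count with half-credit
# ties over all positive x negative pairs.
mw_auc_oracle <- function(scores, y) {
  sp <- scores[y == 1]
  sn <- scores[y == 0]
  total <- 0
  for (p in sp) total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  total / (length(sp) * length(sn))
}

# Brute-force RP features for one pair, recomputed from raw views with
# median baselines only (use on tables where every view has n <= 100).
brute_features <- function(table, a, b) {
  m <- pair_scores(table, a, b)
  one_side <- function(axis, id, partner) {
    v <- entity_view(table, axis, id)
    ord <- order(-v$score, v$partner, method = "radix")
    s <- v$score[ord]
    pct <- percentile_oracle(s)
    r <- pct[match(partner, v$partner[ord])]
    cut_s <- median(s)
    dist <- abs(s - cut_s)  # nearest to median, ties toward better rank
    cut_r <- pct[which(dist <= min(dist) + 1e-12)[1]]
    mu <- mean(s)
    sigma <- sqrt(mean((s - mu)^2))
    list(r = r, cut_s = cut_s, cut_r = cut_r, mu = mu, sigma = sigma)
  }
  A <- one_side("A", a, b)
  B <- one_side("B", b, a)
  c(raw_score = m, rxy = A$r, ryx = B$r,
    arro = (1 - A$r) * (1 - B$r),
    rxt = A$cut_r, sxt = A$cut_s, ryt = B$cut_r, syt = B$cut_s,
    pdx = A$cut_r - A$r, pdy = B$cut_r - B$r,
    fdx = (m - A$cut_s) / max(A$cut_s, 1e-6),
    fdy = (m - B$cut_s) / max(B$cut_s, 1e-6),
    stdx = if (A$sigma > 0) (m - A$mu) / A$sigma else 0,
    stdy = if (B$sigma > 0) (m - B$mu) / B$sigma else 0)
}

# Separable toy feature table over the fixed RP columns: label decided by
# raw_score with a wide margin, all other columns noise.
separable_toy <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    f <- as.data.frame(matrix(runif(n * 14), n, 14))
    names(f) <- rpcascade:::RP_FEATURE_COLUMNS
    f$raw_score <- ifelse(y == 1, runif(n, 0.8, 1), runif(n, 0, 0.2))
    f$label <- y
    f
  })
}
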