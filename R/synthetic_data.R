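#' Synthetic score tables with planted reciprocal structure
#'
#' Emulates the inputs of an integrative pairwise predictor: a sparse
#' bipartite score table (not every pair is scored; per-entity view sizes
#' vary), per-entity baseline shifts that make any single global score
#' threshold suboptimal, a high-scoring head on each dense curve so a knee
#' exists, planted positive interactions carrying a score lift above their
#' entity-pair context, and a recency tag on a fraction of positives for
#' train/test splitting.
#'
#' Each entity receives a latent additive offset ~ Normal(0, baseline_spread).
#' A uniformly chosen subset of pairs (density of the full bipartite grid) is
#' scored as sigmoid(mu0 + offset_a + offset_b + signal * positive +
#' signal * head + noise): planted positives and a per-A-entity "head"
#' fraction (unvalidated but genuinely high-scoring, emulating true
#' interactions the databases have not caught up with) get the lift.
#'
#' @name synthetic_data
NULL

#' Synthetic-data configuration
#'
#' @param n_a,n_b Number of A-side (miRNA-like) and B-side (gene-like)
#'   entities. Defaults 60 x 400 give dense (n > 100) A-side curves and
#'   sparse (n <= 100) B-side curves, exercising both baseline branches.
#' @param density Fraction of the n_a x n_b grid that is scored.
#' @param pos_rate Fraction of scored pairs planted as validated positives.
#' @param baseline_spread SD of the per-entity latent offsets (logit scale);
#'   the reciprocal structure the rescoring exploits.
#' @param signal Logit-scale score lift of positives (and head pairs).
#' @param noise_sd SD of the logit-scale score noise.
#' @param knee_frac Fraction of each A-entity's pairs lifted into its
#'   high-scoring head (disjoint from the positives).
#' @param tag_fraction Fraction of positives tagged `"test_recent"`.
#' @param mu0 Logit-scale intercept; negative keeps background scores low.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_a = 60L, n_b = 400L, density = 0.6,
                         pos_rate = 0.1, baseline_spread = 1.5,
                         signal = 1.5, noise_sd = 0.5, knee_frac = 0.1,
                         tag_fraction = 0.2, mu0 = -2, seed = 1L) {
  cfg <- list(n_a = as.integer(n_a), n_b = as.integer(n_b),
              density = density, pos_rate = pos_rate,
              baseline_spread = baseline_spread, signal = signal,
              noise_sd = noise_sd, knee_frac = knee_frac,
              tag_fraction = tag_fraction, mu0 = mu0,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_a >= 1L, n_b >= 1L,
              density > 0, density <= 1,
              pos_rate > 0, pos_rate <= 1,
              knee_frac >= 0, knee_frac <= 1,
              tag_fraction >= 0, tag_fraction <= 1,
              baseline_spread >= 0, noise_sd >= 0)
    if (n_a * n_b * density < 100) {
      stop("config too small: need n_a * n_b * density >= 100", call. = FALSE)
    }
  })
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic score table, label set and ground truth
#'
#' @param cfg A [synth_config()].
#' @return List with `table` (a `score_table`), `labels` (a `label_set`
#'   whose positives carry the `"test_recent"` tag on a `tag_fraction`
#'   subset), and `truth` (list: `pairs` data.frame with the latent values
#'   and planted roles; `offsets_a`, `offsets_b` named numeric vectors;
#'   `head_counts` intended head size per A entity, the planted knee
#'   location).
#' @export
generate_synth <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    a_ids <- sprintf("mirna_%03d", seq_len(cfg$n_a))
    b_ids <- sprintf("gene_%04d", seq_len(cfg$n_b))
    offsets_a <- stats::setNames(
      stats::rnorm(cfg$n_a, 0, cfg$baseline_spread), a_ids)
    offsets_b <- stats::setNames(
      stats::rnorm(cfg$n_b, 0, cfg$baseline_spread), b_ids)

    n_grid <- cfg$n_a * cfg$n_b
    n_scored <- round(cfg$density * n_grid)
    scored <- sample.int(n_grid, n_scored)          # exact density
    ai <- ((scored - 1L) %% cfg$n_a) + 1L
    bi <- ((scored - 1L) %/% cfg$n_a) + 1L

    n_pos <- max(1L, round(cfg$pos_rate * n_scored))
    is_pos <- logical(n_scored)
    is_pos[sample.int(n_scored, n_pos)] <- TRUE

    # per-A-entity head: lifted but unvalidated pairs, disjoint from positives
    is_head <- logical(n_scored)
    head_counts <- integer(cfg$n_a)
    for (i in seq_len(cfg$n_a)) {
      rows <- which(ai == i & !is_pos)
      k <- round(cfg$knee_frac * sum(ai == i))
      head_counts[i] <- k
      if (k > 0L && length(rows)) {
        is_head[sample(rows, min(k, length(rows)))] <- TRUE
      }
    }

    latent <- cfg$mu0 + offsets_a[ai] + offsets_b[bi] +
      cfg$signal * (is_pos | is_head) +
      stats::rnorm(n_scored, 0, cfg$noise_sd)
    score <- stats::plogis(latent)

    pairs <- data.frame(a = a_ids[ai], b = b_ids[bi], score = score,
                        stringsAsFactors = FALSE)
    dropped <- c(setdiff(a_ids, pairs$a), setdiff(b_ids, pairs$b))
    if (length(dropped)) {
      message(length(dropped), " entities had no scored pairs and were dropped")
    }
    table <- new_score_table(pairs)

    pos <- pairs[is_pos, c("a", "b")]
    tag <- rep(NA_character_, nrow(pos))
    n_tag <- round(cfg$tag_fraction * nrow(pos))
    if (n_tag > 0L) tag[sample.int(nrow(pos), n_tag)] <- "test_recent"
    pos$tag <- tag
    rownames(pos) <- NULL
    labels <- new_label_set(pos)

    truth <- list(
      pairs = data.frame(a = pairs$a, b = pairs$b, score = score,
                         latent = latent, positive = is_pos,
                         head = is_head, stringsAsFactors = FALSE),
      offsets_a = offsets_a, offsets_b = offsets_b,
      head_counts = stats::setNames(head_counts, a_ids)
    )
    list(table = table, labels = labels, truth = truth, config = cfg)
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits `scores.tsv`, `labels.tsv` and `truth.tsv`.
#'
#' @param sim Result of [generate_synth()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_synth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scores(sim$table, file.path(dir, "scores.tsv"))
  pos <- sim$labels$positives
  pos$tag[is.na(pos$tag)] <- ""
  utils::write.table(pos, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$pairs, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
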