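#' End-to-end cascaded rescoring
#'
#' Convenience wrapper over the full pipeline: filter the label set against
#' the score table, compute One-to-All curves and baselines, assemble
#' balanced recency-split train/test sets, train the cascade, refine the
#' test scores, and evaluate refined vs original with a paired bootstrap.
#'
#' @param table A `score_table`.
#' @param labels A `label_set`.
#' @param config A [model_config()].
#' @param test_tag Recency tag marking test positives (`NULL` for a random
#'   split).
#' @param test_fraction Test fraction when `test_tag` is `NULL`.
#' @param n_boot Bootstrap iterations for the evaluation.
#' @param seed Integer seed driving the split, sampling, training and
#'   bootstrap.
#' @param span,sensitivity Baseline-estimation parameters, see
#'   [locate_baseline()].
#' @return List with `model`, `ctx` (curves/baselines), `datasets`
#'   (train/test feature tables), `test_scores` (data.frame `a`, `b`,
#'   `label`, `original`, `refined`, `dos`), and `report` (an
#'   `eval_report`).
#' @export
rp_rescore <- function(table, labels, config = model_config("gbm"),
                       test_tag = "test_recent", test_fraction = 0.05,
                       n_boot = 1000L, seed = 1L, span = 0.3,
                       sensitivity = 1.0) {
  flt <- filter_labels(table, labels)
  table <- flt$table
  labels <- flt$labels
  ctx <- compute_baselines(table, span = span, sensitivity = sensitivity)
  datasets <- assemble_datasets(table, ctx, labels, test_tag = test_tag,
                                test_fraction = test_fraction, seed = seed)
  model <- train_cascade(datasets$train, datasets$train$label,
                         config = config, seed = seed)
  refined <- predict(model, datasets$test)
  original <- datasets$test$raw_score
  report <- evaluate_rescoring(refined, original, datasets$test$label,
                               n_boot = n_boot, seed = seed)
  test_scores <- data.frame(
    a = datasets$test$a, b = datasets$test$b,
    label = datasets$test$label, original = original,
    refined = refined, dos = dos(refined, original),
    stringsAsFactors = FALSE
  )
  list(model = model, ctx = ctx, datasets = datasets,
       test_scores = test_scores, report = report)
}
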