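#' Cascaded second-stage classifiers
#'
#' The cascade takes the initial predictor's score plus the thirteen RP
#' context features and re-scores each pair with a supervised model trained
#' on validated positives and uniformly sampled unvalidated pairs as
#' presumed negatives. Two learners are supported: gradient-boosted trees
#' (xgboost; logistic objective, AUC eval, eta 0.3, gamma 0, max depth 6,
#' 200 rounds, early stopping 5) and a random forest (ranger; 100 trees,
#' max depth 19, 4 candidate features per split).
#'
#' @name cascade_model
NULL

#' Default model configurations
#'
#' @param kind `"gbm"` (gradient boosting) or `"rf"` (random forest).
#' @param ... Overrides of the defaults listed below.
#' @return A `model_config` list.
#' @export
model_config <- function(kind = c("gbm", "rf"), ...) {
  kind <- match.arg(kind)
  cfg <- if (kind == "gbm") {
    list(kind = "gbm", learning_rate = 0.3, gamma = 0, max_depth = 6,
         rounds = 200, early_stopping = 5, objective = "binary:logistic",
         eval_metric = "auc", validation_fraction = 0.1)
  } else {
    list(kind = "rf", n_trees = 100, max_depth = 19,
         max_features_per_split = 4)
  }
  utils::modifyList(cfg, list(...))
}

#' Uniform negative sampling from unvalidated scored pairs
#'
#' Validated non-interactions are essentially unavailable, so unvalidated
#' scored pairs are presumed negative and sampled uniformly without
#' replacement to the requested count.
#'
#' @param table A `score_table`.
#' @param labels A `label_set` (its positives are excluded from the pool).
#' @param count Number of negatives to draw.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param exclude Optional data.frame (`a`, `b`) of extra pairs to keep out
#'   of the pool (e.g. negatives already drawn for another partition).
#' @return data.frame with columns `a`, `b`.
#' @export
sample_negatives <- function(table, labels, count, seed, exclude = NULL) {
  p <- table$pairs
  banned <- pair_key(labels$positives$a, labels$positives$b)
  if (!is.null(exclude) && nrow(exclude)) {
    banned <- c(banned, pair_key(exclude$a, exclude$b))
  }
  pool <- which(!(pair_key(p$a, p$b) %in% banned))
  if (count > length(pool)) {
    stop(sprintf("requested %d negatives but pool has only %d unvalidated pairs",
                 count, length(pool)), call. = FALSE)
  }
  if (count == 0L) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- withr::with_seed(seed, sample(pool, count, replace = FALSE))
  data.frame(a = p$a[idx], b = p$b[idx], stringsAsFactors = FALSE)
}

#' Split validated positives into training and test sets
#'
#' With a recency tag (e.g. interactions new to the latest database
#' release), tagged positives form the held-out test set and all others
#' train — this avoids testing on interactions the upstream predictor may
#' have seen. Without a tag, a seeded random split is used.
#'
#' @param labels A `label_set`.
#' @param test_tag Tag value marking test positives, or `NULL` for a random
#'   split.
#' @param test_fraction Test fraction for the random split (default 0.05).
#' @param seed Seed for the random split.
#' @return List with data.frames `train` and `test` (columns `a`, `b`, `tag`).
#' @export
split_labels <- function(labels, test_tag = NULL, test_fraction = 0.05,
                         seed = 1L) {
  pos <- labels$positives
  if (!is.null(test_tag)) {
    is_test <- !is.na(pos$tag) & pos$tag == test_tag
    if (!any(is_test)) {
      stop("no positive carries test tag '", test_tag, "'", call. = FALSE)
    }
  } else {
    n_test <- max(1L, round(test_fraction * nrow(pos)))
    idx <- withr::with_seed(seed, sample.int(nrow(pos), n_test))
    is_test <- seq_len(nrow(pos)) %in% idx
  }
  if (all(is_test)) stop("empty training side after split", call. = FALSE)
  list(train = pos[!is_test, , drop = FALSE],
       test = pos[is_test, , drop = FALSE])
}

#' Assemble balanced labelled train/test feature sets
#'
#' Splits positives by recency, samples an equal number of negatives per
#' partition (drawn disjointly, so no test pair can appear among training
#' rows), and extracts RP features for every labelled pair.
#'
#' @param table A `score_table`.
#' @param ctx Curves/baselines from [compute_baselines()].
#' @param labels A `label_set`.
#' @param test_tag,test_fraction,seed Passed to [split_labels()] and the
#'   negative sampler.
#' @return List with data.frames `train` and `test`, each the feature matrix
#'   plus a binary `label` column.
#' @export
assemble_datasets <- function(table, ctx, labels, test_tag = NULL,
                              test_fraction = 0.05, seed = 1L) {
  sp <- split_labels(labels, test_tag = test_tag,
                     test_fraction = test_fraction, seed = seed)
  neg_train <- sample_negatives(table, labels, nrow(sp$train), seed = seed)
  neg_test <- sample_negatives(table, labels, nrow(sp$test),
                               seed = seed + 1L, exclude = neg_train)
  build <- function(pos, neg) {
    pairs <- rbind(pos[, c("a", "b")], neg[, c("a", "b")])
    f <- batch_features(table, ctx, pairs)
    f$label <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
    f
  }
  list(train = build(sp$train, neg_train),
       test = build(sp$test, neg_test))
}

feature_matrix <- function(features) {
  missing <- setdiff(RP_FEATURE_COLUMNS, names(features))
  if (length(missing)) {
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(features[, RP_FEATURE_COLUMNS, drop = FALSE])
}

#' Train a cascade model
#'
#' For the gbm a seeded 10% of the training rows is held out to drive early
#' stopping. Feature importance is recorded as gain (gbm) or impurity
#' decrease (rf).
#'
#' @param features Feature data.frame containing the fixed RP columns.
#' @param y Binary labels (0/1), one per row.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An `rp_model`: list with `fit`, `kind`, `config`, `seed`,
#'   `schema`, `best_iteration` (gbm), `importance`.
#' @export
train_cascade <- function(features, y, config = model_config("gbm"),
                          seed = 1L) {
  X <- feature_matrix(features)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("non-finite value in feature matrix", call. = FALSE)
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (config$kind == "gbm") {
    n <- nrow(X)
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- withr::with_seed(seed, sample.int(n, n_val))
    dtrain <- xgboost::xgb.DMatrix(X[-val_idx, , drop = FALSE],
                                   label = y[-val_idx])
    dval <- xgboost::xgb.DMatrix(X[val_idx, , drop = FALSE],
                                 label = y[val_idx])
    fit <- withr::with_seed(seed, xgboost::xgb.train(
      params = list(objective = config$objective,
                    eval_metric = config$eval_metric,
                    eta = config$learning_rate, gamma = config$gamma,
                    max_depth = config$max_depth, nthread = 1),
      data = dtrain, nrounds = config$rounds,
      evals = list(val = dval),
      early_stopping_rounds = config$early_stopping, verbose = 0
    ))
    imp <- xgboost::xgb.importance(model = fit)
    importance <- stats::setNames(imp$Gain, imp$Feature)
    best <- xgboost::xgb.attr(fit, "best_iteration")
    best_iteration <- if (is.null(best)) config$rounds else as.integer(best)
    fit_store <- xgboost::xgb.save.raw(fit)
  } else {
    df <- as.data.frame(X)
    df$.label <- factor(y, levels = c(0L, 1L))
    fit <- withr::with_seed(seed, ranger::ranger(
      dependent.variable.name = ".label", data = df,
      num.trees = config$n_trees, max.depth = config$max_depth,
      mtry = config$max_features_per_split, probability = TRUE,
      importance = "impurity", num.threads = 1, seed = seed
    ))
    importance <- fit$variable.importance
    best_iteration <- NA_integer_
    fit_store <- fit
  }
  structure(
    list(fit = fit_store, kind = config$kind, config = config, seed = seed,
         schema = RP_FEATURE_COLUMNS, best_iteration = best_iteration,
         importance = importance),
    class = "rp_model"
  )
}

#' @export
print.rp_model <- function(x, ...) {
  cat(sprintf("<rp_model> %s over %d features (seed %d)\n",
              x$kind, length(x$schema), x$seed))
  invisible(x)
}

#' Refined scores from a trained cascade model
#'
#' @param object An `rp_model`.
#' @param features Feature data.frame; its RP columns must match the
#'   training schema.
#' @param ... Unused.
#' @return Numeric vector of probability-scale refined scores in [0, 1].
#' @export
predict.rp_model <- function(object, features, ...) {
  present <- intersect(names(features), c(object$schema, "a", "b", "label"))
  extra <- setdiff(names(features), present)
  missing <- setdiff(object$schema, names(features))
  if (length(missing) || length(extra)) {
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  X <- as.matrix(features[, object$schema, drop = FALSE])
  if (object$kind == "gbm") {
    fit <- xgboost::xgb.load.raw(object$fit)
    as.numeric(predict(fit, xgboost::xgb.DMatrix(X)))
  } else {
    as.numeric(predict(object$fit, data = as.data.frame(X),
                       num.threads = 1)$predictions[, "1"])
  }
}

#' Difference of Scores
#'
#' DoS = refined score minus original score. A strongly positive DoS flags a
#' pair the initial predictor scored low but the cascade scores high — a
#' putative false negative of the initial predictor.
#'
#' @param refined,original Equal-length numeric vectors.
#' @return Elementwise `refined - original`.
#' @export
dos <- function(refined, original) {
  if (length(refined) != length(original)) {
    stop(sprintf("length mismatch: refined %d vs original %d",
                 length(refined), length(original)), call. = FALSE)
  }
  refined - original
}

#' Save / load a cascade model
#'
#' The on-disk container embeds the feature schema, config and seed;
#' [predict.rp_model()] refuses a feature table whose columns do not match
#' the stored schema.
#'
#' @param model An `rp_model`.
#' @param path File path.
#' @return `save_model` the path, invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rp_model") ||
      !identical(model$schema, RP_FEATURE_COLUMNS)) {
    stop("file does not contain a compatible cascade model", call. = FALSE)
  }
  model
}
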