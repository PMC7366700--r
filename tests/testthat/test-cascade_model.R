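test_that("negative sampling is uniform, seeded and respects the pool", {
  df <- random_table(12, n_a = 3, n_b = 4, seed = 61)
  tab <- tsv_table(df)
  pos_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(df$a[1:2], df$b[1:2], sep = "\t"), pos_path)
  labs <- load_labels(pos_path)

  whole <- sample_negatives(tab, labs, 10, seed = 1)
  expect_equal(nrow(whole), 10)
  expect_equal(sort(paste(whole$a, whole$b)),
               sort(paste(df$a[-(1:2)], df$b[-(1:2)])))

  expect_equal(nrow(sample_negatives(tab, labs, 0, seed = 1)), 0)
  expect_error(sample_negatives(tab, labs, 11, seed = 1), "pool has only 10")
  expect_identical(sample_negatives(tab, labs, 5, seed = 9),
                   sample_negatives(tab, labs, 5, seed = 9))
})

test_that("overlap of two independent draws matches the hypergeometric rate", {
  n_a <- 100; n_b <- 100
  grid <- expand.grid(a = sprintf("m%03d", 1:n_a),
                      b = sprintf("g%03d", 1:n_b),
                      stringsAsFactors = FALSE)
  grid$score <- withr::with_seed(62, runif(nrow(grid)))
  tab <- tsv_table(grid)
  labs <- rpcascade:::new_label_set(
    data.frame(a = "m001", b = "g001", tag = NA_character_))
  d1 <- sample_negatives(tab, labs, 2000, seed = 1)
  d2 <- sample_negatives(tab, labs, 2000, seed = 2)
  overlap <- length(intersect(paste(d1$a, d1$b), paste(d2$a, d2$b)))
  # E[overlap] = 2000 * 2000/9999 ~ 400; binomial 99% bounds
  expect_gt(overlap, 400 - 3 * sqrt(2000 * 0.2 * 0.8))
  expect_lt(overlap, 400 + 3 * sqrt(2000 * 0.2 * 0.8))
})

test_that("recency-tagged positives form the test side of the split", {
  pos <- data.frame(a = sprintf("m%03d", 1:100), b = "g1",
                    tag = c(rep("v8_new", 5), rep(NA, 95)))
  labs <- rpcascade:::new_label_set(pos)
  sp <- split_labels(labs, test_tag = "v8_new")
  expect_equal(nrow(sp$train), 95)
  expect_equal(nrow(sp$test), 5)
  expect_true(all(sp$test$tag == "v8_new"))
  expect_error(split_labels(labs, test_tag = "absent_tag"), "absent_tag")

  # untagged: seeded random split is reproducible
  labs2 <- rpcascade:::new_label_set(transform(pos, tag = NA_character_))
  s1 <- split_labels(labs2, test_fraction = 0.2, seed = 5)
  s2 <- split_labels(labs2, test_fraction = 0.2, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$test), 20)
})

test_that("training learns separable data and rejects degenerate input", {
  toy <- separable_toy(n = 80)
  for (kind in c("gbm", "rf")) {
    model <- train_cascade(toy, toy$label, model_config(kind), seed = 3)
    p <- predict(model, toy)
    expect_equal(roc_pr_auc(p, toy$label)$roc_auc, 1.0)
    expect_true(all(p[toy$label == 1] > 0.5))
    expect_true(all(p[toy$label == 0] < 0.5))
    expect_true(length(model$importance) >= 1)
  }
  expect_error(train_cascade(toy, rep(1L, nrow(toy)), model_config("gbm")),
               "single class")
  toy_na <- toy
  toy_na$rxy[1] <- NA
  expect_error(train_cascade(toy_na, toy$label, model_config("gbm")),
               "non-finite")
})

test_that("labels independent of features give chance-level held-out AUC", {
  withr::with_seed(71, {
    n <- 2000
    f <- as.data.frame(matrix(runif(n * 14), n, 14))
    names(f) <- rpcascade:::RP_FEATURE_COLUMNS
    y <- rep(c(0L, 1L), n / 2)
    hold <- seq_len(n) %in% sample.int(n, 500)
    model <- train_cascade(f[!hold, ], y[!hold], model_config("gbm"),
                           seed = 7)
    auc <- roc_pr_auc(predict(model, f[hold, ]), y[hold])$roc_auc
    expect_gt(auc, 0.45)
    expect_lt(auc, 0.55)
  })
})

test_that("prediction is deterministic, permutation-equivariant and schema-checked", {
  toy <- separable_toy(n = 100, seed = 8)
  model <- train_cascade(toy, toy$label, model_config("gbm"), seed = 8)
  p1 <- predict(model, toy)
  expect_identical(predict(model, toy), p1)
  expect_true(all(p1 >= 0 & p1 <= 1))

  perm <- withr::with_seed(9, sample.int(nrow(toy)))
  expect_equal(predict(model, toy[perm, ]), p1[perm])

  bad <- toy[, -match("arro", names(toy))]
  expect_error(predict(model, bad), "arro")
  bad2 <- toy
  bad2$bogus <- 1
  expect_error(predict(model, bad2), "bogus")
})

test_that("models round-trip through disk with schema intact", {
  toy <- separable_toy(n = 60, seed = 10)
  for (kind in c("gbm", "rf")) {
    model <- train_cascade(toy, toy$label, model_config(kind), seed = 10)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(model, path)
    model2 <- load_model(path)
    expect_equal(predict(model2, toy), predict(model, toy))
  }
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(no = "model"), junk)
  expect_error(load_model(junk), "compatible")
})

test_that("difference of scores is elementwise and bounded", {
  expect_equal(dos(0.9868, 0.0070), 0.9798, tolerance = 1e-12)
  expect_equal(dos(0.5, 0.5), 0)
  expect_equal(dos(c(0.9, 0.1), c(0.4, 0.6)), c(0.5, -0.5))
  expect_error(dos(1:3 / 10, 1:2 / 10), "length mismatch")
  r <- withr::with_seed(11, runif(100))
  o <- withr::with_seed(12, runif(100))
  expect_true(all(dos(r, o) >= -1 & dos(r, o) <= 1))
})

test_that("assembled datasets are balanced and train/test disjoint", {
  sim <- generate_synth(synth_config(n_a = 20, n_b = 80, density = 0.8,
                                     pos_rate = 0.15, seed = 13))
  flt <- filter_labels(sim$table, sim$labels)
  ctx <- compute_baselines(flt$table)
  ds <- assemble_datasets(flt$table, ctx, flt$labels,
                          test_tag = "test_recent", seed = 13)
  expect_equal(sum(ds$train$label == 1), sum(ds$train$label == 0))
  expect_equal(sum(ds$test$label == 1), sum(ds$test$label == 0))
  train_keys <- paste(ds$train$a, ds$train$b)
  test_keys <- paste(ds$test$a, ds$test$b)
  expect_length(intersect(train_keys, test_keys), 0)
})

test_that("the seeded pipeline is reproducible end to end", {
  sim <- generate_synth(synth_config(n_a = 15, n_b = 60, density = 0.8,
                                     pos_rate = 0.2, seed = 17))
  run <- function() {
    res <- rp_rescore(sim$table, sim$labels, n_boot = 20, seed = 17)
    res$test_scores
  }
  expect_identical(run(), run())
})
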