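test_that("ROC/PR AUC hit exact values on perfectly ordered scores", {
  y <- rep(c(1L, 0L), each = 10)
  perfect <- c(seq(1, 0.6, length.out = 10), seq(0.4, 0, length.out = 10))
  a <- roc_pr_auc(perfect, y)
  expect_equal(a$roc_auc, 1.0)
  expect_equal(a$pr_auc, 1.0)

  anti <- rev(perfect)
  expect_equal(roc_pr_auc(anti, y)$roc_auc, 0.0)
  expect_error(roc_pr_auc(runif(5), rep(1L, 5)), "both classes")
})

test_that("ROC AUC equals the Mann-Whitney oracle, ties at half credit", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 40
      scores <- round(runif(n), 1)  # coarse grid forces ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
      expect_equal(roc_pr_auc(scores, y)$roc_auc, mw_auc_oracle(scores, y))
    })
  }
})

test_that("ROC AUC agrees with an independent library on clean instances", {
  skip_if_not_installed("pROC")
  withr::with_seed(99, {
    scores <- runif(200)
    y <- rbinom(200, 1, 0.4)
    ours <- roc_pr_auc(scores, y)$roc_auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref)
  })
})

test_that("bootstrap AUC is seeded, consistent and stratified", {
  withr::with_seed(101, {
    n <- 400
    y <- rep(c(1L, 0L), each = n / 2)
    scores <- y * 0.3 + runif(n) * 0.7
  })
  b1 <- bootstrap_auc(list(m = scores), y, n_boot = 200, seed = 5)
  b2 <- bootstrap_auc(list(m = scores), y, n_boot = 200, seed = 5)
  expect_identical(b1$roc, b2$roc)
  point <- roc_pr_auc(scores, y)$roc_auc
  mu <- b1$summary$roc_auc_mean
  sigma <- b1$summary$roc_auc_sd
  expect_lt(abs(mu - point), 2 * sigma)

  expect_error(bootstrap_auc(list(m = rep(0.5, 20)),
                             rep(c(0L, 1L), 10), n_boot = 10),
               "constant")
  expect_error(bootstrap_auc(list(m = scores), y, n_boot = 1), "n_boot")
})

test_that("bootstrap sd shrinks as the test set grows", {
  sds <- vapply(c(200, 800, 3200), function(n) {
    withr::with_seed(n, {
      y <- rep(c(1L, 0L), each = n / 2)
      scores <- y * 0.3 + runif(n) * 0.7
    })
    bootstrap_auc(list(m = scores), y, n_boot = 200,
                  seed = 3)$summary$roc_auc_sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("Welch test matches its contract on forced cases", {
  x <- withr::with_seed(7, rnorm(50))
  expect_equal(welch_test(x, x), 1)
  a <- withr::with_seed(8, rnorm(1000, 0, 1))
  b <- withr::with_seed(9, rnorm(1000, 5, 1))
  expect_lt(welch_test(a, b), 1e-10)
  expect_error(welch_test(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(welch_test(1, 1:5), ">= 2")
  # agreement with the reference implementation
  expect_equal(welch_test(a, b),
               stats::t.test(a, b, var.equal = FALSE)$p.value)
})

test_that("combined scores follow the printed weighting and boundaries", {
  expect_equal(combined_score(0.4, 0.8, lambda = 0.5), 0.08)
  m <- withr::with_seed(10, runif(50))
  r <- withr::with_seed(11, runif(50))
  expect_equal(combined_score(m, r, lambda = 0), rep(0, 50))
  expect_equal(combined_score(m, r, lambda = 1), rep(0, 50))
  expect_error(combined_score(m, r, lambda = 1.2), "lambda")

  # any lambda in (0,1) ranks identically to the plain product
  base_rank <- order(m * r)
  for (lam in c(0.1, 0.5, 0.9)) {
    expect_equal(order(combined_score(m, r, lam)), base_rank)
  }
  norm <- combined_score(m, r, 0.5, normalize = TRUE)
  expect_equal(range(norm), c(0, 1))
})

test_that("DoS candidate tables filter and sort correctly", {
  pairs <- data.frame(a = c("m1", "m2"), b = c("g1", "g2"))
  out <- dos_candidates(pairs, refined = c(0.9, 0.6),
                        original = c(0.3, 0.2))
  expect_equal(nrow(out$by_dos), 1)
  expect_equal(out$by_dos$a, "m1")

  none <- dos_candidates(pairs, c(0.5, 0.6), c(0.4, 0.3))
  expect_equal(nrow(none$by_dos), 0)
  expect_equal(nrow(none$by_refined), 0)

  withr::with_seed(12, {
    n <- 100
    pr <- data.frame(a = sprintf("m%03d", 1:n), b = sprintf("g%03d", 1:n))
    refined <- runif(n)
    original <- runif(n) * 0.3
  })
  both <- dos_candidates(pr, refined, original, threshold = 0.5)
  d <- refined - original
  keep <- d >= 0.5
  expect_equal(nrow(both$by_dos), sum(keep))
  expect_equal(both$by_dos$dos, sort(d[keep], decreasing = TRUE))
  expect_equal(both$by_refined$refined,
               sort(refined[keep], decreasing = TRUE))
})

test_that("confidence tiers are nested, exhaustive and score-ordered", {
  scores100 <- withr::with_seed(13, sample(seq(0.01, 1, by = 0.01)))
  t100 <- tier_assignment(scores100)
  expect_equal(as.vector(table(t100)), c(1, 4, 5, 23, 67))

  # N=3: every cumulative cut is ceil(frac*3)=1, so only the top score
  # is tiered and the rest fall to bottom66
  expect_equal(as.character(tier_assignment(c(0.9, 0.5, 0.1))),
               c("top1", "bottom66", "bottom66"))

  withr::with_seed(14, {
    s <- runif(1000)
    tiers <- tier_assignment(s)
    expect_equal(length(s), sum(table(tiers)))
    top <- tiers != "bottom66"
    expect_gte(min(s[top]), max(s[!top]))
  })
})

test_that("the evaluation report compares refined against original", {
  withr::with_seed(15, {
    n <- 300
    y <- rep(c(1L, 0L), each = n / 2)
    refined <- y * 0.5 + runif(n) * 0.5
    original <- y * 0.1 + runif(n) * 0.9
  })
  rep_ <- evaluate_rescoring(refined, original, y, n_boot = 100, seed = 16)
  expect_gt(rep_$boot$summary$roc_auc_mean[1],
            rep_$boot$summary$roc_auc_mean[2])
  expect_lt(rep_$p_value_roc, 0.001)
  expect_true(all(rep_$boot$summary$roc_auc_sd >= 0))
  expect_gte(rep_$p_value_pr, 0)
  expect_lte(rep_$p_value_pr, 1)
})
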