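test_that("ranksum labelling marks the extremes with average ranks on ties", {
  # 5 samples with identical orderings: ranksums (10, 8, 6, 4, 2)
  d <- tibble::tibble(sample = letters[1:5], expression = 5:1,
                      copy_number = 5:1)
  lab <- ranksum_label(d, top_fraction = 0.2)
  expect_equal(lab$ranksum, c(10, 8, 6, 4, 2))
  expect_equal(lab$label, c("high", "unlabeled", "unlabeled", "unlabeled", "low"))

  # 10 samples, top_fraction 0.1: exactly the joint max high, joint min low
  d10 <- tibble::tibble(sample = sprintf("s%02d", 1:10), expression = 10:1,
                        copy_number = 10:1)
  lab10 <- ranksum_label(d10, top_fraction = 0.1)
  expect_equal(lab10$label[1], "high")
  expect_equal(lab10$label[10], "low")
  expect_equal(sum(lab10$label == "unlabeled"), 8)

  # perfect anticorrelation: all ranksums tie; id order breaks them, warning
  danti <- tibble::tibble(sample = letters[1:6], expression = 1:6,
                          copy_number = 6:1)
  expect_warning(laba <- ranksum_label(danti, top_fraction = 1 / 6), "tie")
  expect_equal(sum(laba$label == "high"), 1)
  expect_equal(sum(laba$label == "low"), 1)

  # "all" mode: median split, ties to the low class
  dall <- tibble::tibble(sample = letters[1:4], expression = c(4, 3, 2, 1),
                         copy_number = c(4, 3, 2, 1))
  laball <- ranksum_label(dall, mode = "all")
  expect_equal(laball$label, c("high", "high", "low", "low"))

  expect_error(ranksum_label(d, top_fraction = 0.05), "Too few")
})

test_that("naive Bayes moments match hand computation and e1071", {
  expr <- rbind(
    gA = c(2, 4, 10, 12),
    gB = c(1, 1, 1, 1),          # constant gene: variance floor applies
    gC = c(5, 6, 1, 2)
  )
  colnames(expr) <- paste0("s", 1:4)
  labels <- tibble::tibble(sample = paste0("s", 1:4),
                           label = c("low", "low", "high", "high"))
  fit <- nb_fit(expr, labels, log2_transform = FALSE)
  td <- tidy(fit)
  expect_equal(td$mean_high[td$gene_id == "gA"], 11)
  expect_equal(td$mean_low[td$gene_id == "gA"], 3)
  expect_equal(td$var_high[td$gene_id == "gA"], 2)  # unbiased variance
  expect_gt(td$var_high[td$gene_id == "gB"], 0)     # floored, not zero
  expect_equal(glance(fit)$prior_high, 0.5)

  # cross-check parameters against the reference naive Bayes implementation
  skip_if_not_installed("e1071")
  ref <- e1071::naiveBayes(x = t(expr), y = factor(labels$label))
  expect_equal(unname(td$mean_high[td$gene_id == "gA"]),
               unname(ref$tables$gA["high", 1]))
  expect_equal(unname(td$mean_low[td$gene_id == "gC"]),
               unname(ref$tables$gC["low", 1]))
  expect_equal(unname(td$var_high[td$gene_id == "gA"]),
               unname(ref$tables$gA["high", 2])^2)

  expect_error(nb_fit(expr, labels[labels$label == "high", ]), "two training")
})

test_that("posteriors follow the closed-form Gaussian ratio", {
  # symmetric one-gene model: means +/-1, unit variance, equal priors
  expr <- rbind(g1 = c(-1, -1.5, -0.5, 1, 1.5, 0.5))
  colnames(expr) <- paste0("s", 1:6)
  labels <- tibble::tibble(sample = paste0("s", 1:6),
                           label = rep(c("low", "high"), each = 3))
  fit <- nb_fit(expr, labels, log2_transform = FALSE)
  expect_equal(tidy(fit)$mean_high, 1)
  expect_equal(tidy(fit)$mean_low, -1)

  score <- function(x) {
    m <- matrix(x, 1, dimnames = list("g1", "t1"))
    nb_predict(fit, m)$posterior_high
  }
  expect_equal(score(0), 0.5, tolerance = 1e-12)
  # at x = 1 the log-likelihood ratio is 2 (variances 0.25 here scale it);
  # use the model's own variance in the closed form
  v <- tidy(fit)$var_high
  llr <- (stats::dnorm(1, 1, sqrt(v), log = TRUE) -
            stats::dnorm(1, -1, sqrt(v), log = TRUE))
  expect_equal(score(1), 1 / (1 + exp(-llr)), tolerance = 1e-12)
  expect_equal(score(50), 1, tolerance = 1e-9)
  # complementary posteriors sum to one by construction of the normalisation
  expect_equal(score(0.3) + (1 - score(0.3)), 1, tolerance = 1e-12)

  expect_error(nb_predict(fit, matrix(0, 1, 1, dimnames = list("other", "t"))),
               "absent")
})

test_that("AUC equals the exhaustive pair-count oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c("high", "high", "low", "low")), 1)
  expect_equal(auc_score(c(0.9, 0.3, 0.8, 0.4), c("high", "high", "low", "low")), 0.5)
  expect_equal(auc_score(rep(0.5, 6), rep(c("high", "low"), 3)), 0.5)
  expect_error(auc_score(1:3, rep("high", 3)), "Both classes")

  pair_count_auc <- function(scores, pos) {
    tot <- 0
    for (i in which(pos)) for (j in which(!pos)) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / (sum(pos) * sum(!pos))
  }
  withr::with_seed(61, {
    for (rep in 1:25) {
      n <- sample(4:12, 1)
      pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
      expect_equal(auc_score(scores, pos), pair_count_auc(scores, pos))
    }
  })
})

test_that("feature selection recovers planted shifted genes", {
  sim <- gen_expression(n_genes = 70, n_samples = 80, signature_size = 10,
                        effect_size = 3, seed = 62)
  got <- select_features(sim$expr, sim$labels, k = 10)
  expect_gte(length(intersect(got, sim$signature_genes)), 9)

  # one huge-shift gene among nulls, k = 1
  sim1 <- gen_expression(n_genes = 40, n_samples = 60, signature_size = 1,
                         effect_size = 6, seed = 63)
  expect_equal(select_features(sim1$expr, sim1$labels, k = 1),
               sim1$signature_genes)

  # k = all genes returns the full set
  expect_setequal(select_features(sim$expr, sim$labels, k = 70),
                  rownames(sim$expr))
  expect_error(select_features(sim$expr, sim$labels, k = 71), "exceeds")
})

test_that("iterated holdout is deterministic and responds to signal", {
  sim <- gen_expression(n_genes = 60, n_samples = 90, signature_size = 10,
                        effect_size = 3, seed = 64)
  cv1 <- iterated_holdout(sim$expr, sim$labels, sim$signature_genes,
                          n_iterations = 30, seed = 65)
  cv2 <- iterated_holdout(sim$expr, sim$labels, sim$signature_genes,
                          n_iterations = 30, seed = 65)
  expect_equal(cv1$auc, cv2$auc)
  expect_gt(cv1$mean_auc, 0.99)
  expect_equal(length(cv1$auc), 30)
  expect_true(all(cv1$auc >= 0 & cv1$auc <= 1))

  # null labels: mean AUC near one half
  sim0 <- gen_expression(n_genes = 60, n_samples = 90, signature_size = 10,
                         effect_size = 0, seed = 66)
  cv0 <- iterated_holdout(sim0$expr, sim0$labels, n_iterations = 50, seed = 67)
  expect_gt(cv0$mean_auc, 0.4)
  expect_lt(cv0$mean_auc, 0.6)

  # monotone transforms of expression leave the ROC-based evaluation intact
  # (checked through the rank-based AUC on transformed scores)
  sc <- stats::runif(20); lb <- rep(c("high", "low"), 10)
  expect_equal(auc_score(sc, lb), auc_score(exp(3 * sc) + 2, lb))

  expect_error(
    iterated_holdout(sim$expr, sim$labels, c("missing_gene"), n_iterations = 2),
    "missing_gene"
  )

  # broom-style accessors
  expect_equal(nrow(tidy(cv1)), 30)
  expect_equal(glance(cv1)$mean_auc, cv1$mean_auc)
})

test_that("per-fold feature selection inside the holdout keeps performance", {
  sim <- gen_expression(n_genes = 80, n_samples = 90, signature_size = 10,
                        effect_size = 3, seed = 68)
  cv <- iterated_holdout(sim$expr, sim$labels, n_iterations = 15, seed = 69,
                         select_k = 10)
  expect_gt(cv$mean_auc, 0.95)
})
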