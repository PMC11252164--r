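# synthetic evaluated-batch builder: match flag driven by a known
# threshold rule on one column plus label noise
planted_batch <- function(n, seed, rule_col = "p1", threshold = 1,
                          flip_rate = 0.05) {
  withr::with_seed(seed, {
    tb <- tibble::tibble(
      p1 = 10^runif(n, -1, 1),
      p2 = 10^runif(n, -1, 1),
      p3 = 10^runif(n, -1, 1)
    )
    m <- tb[[rule_col]] >= threshold
    flip <- runif(n) < flip_rate
    tb$match <- ifelse(flip, !m, m)
    tb
  })
}

test_that("KS discrimination detects a planted distribution shift", {
  withr::with_seed(99, {
    x_match <- 10^rnorm(200, mean = 1)    # shifted one decade up
    x_other <- 10^rnorm(200, mean = 0)
    tb <- tibble::tibble(p = c(x_match, x_other),
                         q = 10^rnorm(400),
                         match = rep(c(TRUE, FALSE), each = 200))
  })
  res <- ks_discriminate(tb, parameters = c("p", "q"))
  expect_equal(res$parameter[1], "p")
  expect_lt(res$p_value[res$parameter == "p"], 1e-3)
  expect_gt(res$p_value[res$parameter == "q"], 0.01)
  expect_true(all(res$p_adj >= res$p_value - 1e-15))
})

test_that("shuffled labels give small D and roughly uniform p", {
  withr::with_seed(5, {
    tb <- tibble::tibble(p = runif(400), match = sample(c(TRUE, FALSE), 400,
                                                        replace = TRUE))
  })
  res <- ks_discriminate(tb, parameters = "p")
  expect_lt(res$D, 0.15)
  expect_gt(res$p_value, 0.01)
})

test_that("KS ranks the rule parameter first on planted batches", {
  tb <- planted_batch(400, seed = 17)
  res <- ks_discriminate(tb, parameters = c("p1", "p2", "p3"))
  expect_equal(res$parameter[res$rank == 1], "p1")
})

test_that("ROC is perfect for the flag itself and chance for noise", {
  tb <- planted_batch(300, seed = 23, flip_rate = 0)
  tb$exact <- as.numeric(tb$match)
  perfect <- roc_classifier(tb, "exact", "ge")
  expect_equal(attr(perfect, "auc"), 1)
  indep <- roc_classifier(tb, "p2", "ge")
  expect_lt(abs(attr(indep, "auc") - 0.5), 0.1)
})

test_that("ROC recovers the planted threshold and respects direction", {
  tb <- planted_batch(500, seed = 31, threshold = 2, flip_rate = 0)
  roc <- roc_classifier(tb, "p1", "ge")
  expect_gt(attr(roc, "auc"), 0.99)
  # best operating point (tpr - fpr) sits at the planted threshold
  youden <- roc[which.max(roc$tpr - roc$fpr), ]
  sorted <- sort(tb$p1)
  step <- max(diff(sort(unique(round(log10(sorted), 6)))))
  expect_lt(abs(log10(youden$threshold) - log10(2)), 0.1)
  # inverted rule needs the "lt" direction
  tb2 <- tb
  tb2$match <- !tb$match
  roc_lt <- roc_classifier(tb2, "p1", "lt")
  expect_gt(attr(roc_lt, "auc"), 0.99)
})

test_that("AUC is invariant under strictly monotone transforms", {
  tb <- planted_batch(300, seed = 41)
  a1 <- attr(roc_classifier(tb, "p1", "ge"), "auc")
  tb$p1 <- log(tb$p1) * 3 + 7
  a2 <- attr(roc_classifier(tb, "p1", "ge"), "auc")
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  tb <- planted_batch(250, seed = 53, flip_rate = 0.2)
  ours <- attr(roc_classifier(tb, "p1", "ge"), "auc")
  ref <- as.numeric(pROC::auc(pROC::roc(tb$match, tb$p1, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("degenerate single-class batches are rejected", {
  tb <- tibble::tibble(p = runif(20), match = rep(TRUE, 20))
  expect_error(roc_classifier(tb, "p"), "non-empty")
  expect_error(ks_discriminate(tb, parameters = "p"), "non-empty")
})

test_that("GAP-rate sweep: L129Q PLC-beta falls monotonically and collapses", {
  sw <- khyd2_sweep(gq_params("revised"),
                    ratio_grid = c(1, 5, 20, 40, 770))
  l <- sw[sw$genotype == "CYSLTR2:L129Q:het", ]
  expect_true(all(diff(l$active_PLC) <= 1e-12))
  # substantial signal in the accepted 1-40 band, collapse at 770
  expect_gt(min(l$active_PLC[l$ratio <= 40]), 5 * l$active_PLC[l$ratio == 770])
  # the experiment-matching region covers the 1-40 band
  expect_true(all(sw$match[sw$ratio <= 40]))
  expect_false(any(sw$match[sw$ratio == 770]))
})
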