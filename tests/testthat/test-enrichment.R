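test_that("input validation names the violated inequality", {
  expect_error(enrichment_inputs(10, 11, 2, 1), "x <= N")
  expect_error(enrichment_inputs(10, 2, 11, 1), "y <= N")
  expect_error(enrichment_inputs(10, 2, 3, 4), "k <= min")
  expect_error(enrichment_inputs(10, 7, 6, 1), "x \\+ y - k <= N")
  expect_error(enrichment_inputs(10.5, 2, 3, 1), "integers")
})

test_that("closed form equals the hypergeometric point mass exhaustively for N <= 30", {
  worst <- 0
  for (N in 1:30) {
    for (x in 0:N) {
      for (y in 0:N) {
        k <- max(0, x + y - N):min(x, y)
        p1 <- vapply(k, function(kk)
          enrichment_probability(enrichment_inputs(N, x, y, kk)), numeric(1))
        p2 <- stats::dhyper(k, x, N - x, y)
        worst <- max(worst, max(abs(p1 - p2) / pmax(p2, 1e-300)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("hand-enumerable and degenerate cases", {
  # N=2, x=y=k=1: 2 of the 4 equally likely placements coincide
  expect_equal(enrichment_probability(enrichment_inputs(2, 1, 1, 1)), 0.5)
  # forced total overlap
  expect_equal(enrichment_probability(enrichment_inputs(7, 7, 7, 7)), 1)
  # impossible-but-valid zero overlap of two full sets
  expect_equal(enrichment_probability(enrichment_inputs(3, 3, 3, 3)), 1)
})

test_that("normalization and x/y symmetry hold", {
  withr::with_seed(61, {
    for (i in 1:25) {
      N <- sample(5:500, 1)
      x <- sample(0:N, 1); y <- sample(0:N, 1)
      ks <- max(0, x + y - N):min(x, y)
      total <- sum(vapply(ks, function(k)
        enrichment_probability(enrichment_inputs(N, x, y, k)), numeric(1)))
      expect_equal(total, 1, tolerance = 1e-12)
      k <- ks[sample.int(length(ks), 1)]
      expect_equal(enrichment_probability(enrichment_inputs(N, x, y, k)),
                   enrichment_probability(enrichment_inputs(N, y, x, k)),
                   tolerance = 1e-12)
    }
  })
})

test_that("the printed cohort quadruples give the expected probabilities", {
  tcga <- enrichment_test(enrichment_inputs(80, 3, 4, 2), mc_draws = 0)
  expect_equal(tcga$p_point, tcga$p_hypergeom, tolerance = 1e-12)
  expect_equal(tcga$p_point, 5.55e-3, tolerance = 1e-3)
  expect_gte(tcga$p_tail, tcga$p_point)

  ref82 <- enrichment_test(enrichment_inputs(103, 2, 11, 2), mc_draws = 0)
  expect_equal(ref82$p_point, ref82$p_hypergeom, tolerance = 1e-12)
  expect_equal(ref82$p_point, stats::dhyper(2, 2, 101, 11),
               tolerance = 1e-12)
})

test_that("Monte-Carlo estimator is seed-deterministic and agrees with the closed form", {
  inp <- enrichment_inputs(2, 1, 1, 1)
  mc1 <- mc_enrichment(inp, n_draws = 1e5, seed = 3)
  mc2 <- mc_enrichment(inp, n_draws = 1e5, seed = 3)
  expect_identical(mc1$p_mc, mc2$p_mc)
  expect_lt(abs(mc1$p_mc - 0.5), 3 * mc1$se)

  withr::with_seed(71, {
    for (i in 1:20) {
      N <- sample(4:60, 1)
      x <- sample(1:N, 1); y <- sample(1:N, 1)
      ks <- max(0, x + y - N):min(x, y)
      k <- ks[sample.int(length(ks), 1)]
      inp <- enrichment_inputs(N, x, y, k)
      mc <- mc_enrichment(inp, n_draws = 1e4, seed = i)
      p <- enrichment_probability(inp)
      se <- max(mc$se, sqrt(p * (1 - p) / 1e4), 1e-4)
      expect_lt(abs(mc$p_mc - p), 4 * se)
    }
  })
  expect_error(mc_enrichment(inp, n_draws = 100), "1e4")
})

test_that("cohort tables reduce to the correct summary counts", {
  fam <- sema_plexin_genes()
  expect_length(fam, 29)
  coh <- make_cohort(80, 3, 4, 2, seed = 7)
  inp <- table_to_inputs(coh, "CYSLTR2", fam)
  expect_equal(unlist(inp[c("N", "x", "y", "k")]),
               c(N = 80, x = 3, y = 4, k = 2))

  # the packaged fixture encodes the same counts
  fixture <- utils::read.delim(
    system.file("extdata", "synthetic_tcga_like_cohort.tsv",
                package = "gqcycle")
  )
  inp2 <- table_to_inputs(fixture, "CYSLTR2", fam)
  expect_equal(unlist(inp2[c("N", "x", "y", "k")]),
               c(N = 80, x = 3, y = 4, k = 2))

  # no family carriers -> y = k = 0
  none <- tibble::tibble(patient_id = c("a", "b"), gene = c("CYSLTR2", "TP53"))
  inp3 <- table_to_inputs(none, "CYSLTR2", fam)
  expect_equal(c(inp3$y, inp3$k), c(0, 0))

  # wide logical layout
  wide <- tibble::tibble(patient_id = c("a", "b", "c"),
                         CYSLTR2 = c(TRUE, FALSE, TRUE),
                         SEMA3A = c(TRUE, TRUE, FALSE))
  inp4 <- table_to_inputs(wide, "CYSLTR2", fam)
  expect_equal(unlist(inp4[c("N", "x", "y", "k")]),
               c(N = 3, x = 2, y = 2, k = 1))

  expect_error(table_to_inputs(tibble::tibble(), "CYSLTR2", fam), "empty")
})
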