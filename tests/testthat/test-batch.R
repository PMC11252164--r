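test_that("a single-row batch reproduces the single-run simulation exactly", {
  p <- gq_params("initial")
  center <- tibble::tibble(
    k_hyd2 = p$kinetics[["k_hyd2"]],
    effector_bias = effector_bias(p),
    TRIO_tot = p$totals[["TRIO_tot"]]
  )
  ev <- evaluate_batch(center, params = p)
  q <- solve_steady_state(p, "GNAQ:Q209L:het")
  l <- solve_steady_state(p, "CYSLTR2:L129Q:het")
  expect_identical(ev$trio_q209l, q$active_TRIO)
  expect_identical(ev$plc_q209l, q$active_PLC)
  expect_identical(ev$trio_l129q, l$active_TRIO)
  expect_identical(ev$plc_l129q, l$active_PLC)
  expect_true(ev$converged)
})

test_that("apply_row handles composites, dummies, and rejects unknowns", {
  p0 <- gq_params("initial")
  p <- apply_row(p0, list(effector_bias = 8, k_hyd2 = 0.9, dummy_z = 99))
  expect_equal(effector_bias(p), 8)
  expect_equal(p$kinetics[["k_hyd2"]], 0.9)
  expect_error(apply_row(p0, list(not_a_symbol = 1)), "not_a_symbol")
})

test_that("behavior classification follows the weak/strong threshold rule", {
  base <- tibble::tibble(
    trio_q209l = 1, plc_q209l = 1, trio_l129q = 1, plc_l129q = 1,
    converged = TRUE
  )
  mk <- function(ftq, fpq, ftl, fpl) {
    dplyr::mutate(base, fold_trio_q209l = ftq, fold_plc_q209l = fpq,
                  fold_trio_l129q = ftl, fold_plc_l129q = fpl)
  }
  # identical outputs, both activated -> strong on both pathways
  expect_equal(classify_behavior(mk(5, 5, 5, 5))$behavior, "strong_both")
  # equal PLC excess but no TRIO excess for L129Q -> strong ERK, weak YAP
  expect_equal(classify_behavior(mk(5, 5, 1, 5))$behavior,
               "strongERK_weakYAP")
  expect_equal(classify_behavior(mk(5, 5, 5, 1))$behavior,
               "weakERK_strongYAP")
  expect_equal(classify_behavior(mk(5, 5, 1, 1))$behavior, "weak_both")
})

test_that("theta boundary is strict and undefined Q209L folds yield NA", {
  base <- tibble::tibble(
    trio_q209l = 1, plc_q209l = 1, trio_l129q = 1, plc_l129q = 1,
    converged = TRUE
  )
  mk <- function(ftq, fpq, ftl, fpl) {
    dplyr::mutate(base, fold_trio_q209l = ftq, fold_plc_q209l = fpq,
                  fold_trio_l129q = ftl, fold_plc_l129q = fpl)
  }
  # L129Q TRIO excess just below theta * Q209L excess -> weak YAP
  expect_equal(classify_behavior(mk(5, 5, 2.99, 5))$behavior,
               "strongERK_weakYAP")
  # exactly at the threshold -> not weak
  expect_equal(classify_behavior(mk(5, 5, 3, 5))$behavior, "strong_both")
  # Q209L fold <= 1 -> pathway undefined, row excluded
  expect_true(is.na(classify_behavior(mk(1, 5, 2, 5))$behavior))
  fr <- behavior_fractions(mk(1, 5, 2, 5), theta = 0.5)
  expect_equal(sum(fr$n), 0)
})

test_that("behavior fractions sum to one over defined rows and track theta", {
  draws <- random_param_draws(12, seed = 21)
  ev <- evaluate_batch(draws, params = gq_params("initial"))
  fr <- behavior_fractions(ev, theta = c(0.25, 0.5, 0.75))
  sums <- tapply(fr$fraction, fr$theta, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("match flag is the exact published predicate with inclusive PLC", {
  row <- function(tq, pq, tl, pl) {
    tibble::tibble(trio_q209l = tq, plc_q209l = pq,
                   trio_l129q = tl, plc_l129q = pl)
  }
  # ties on both readouts -> FALSE (TRIO must be strictly lower)
  expect_false(match_experiment(row(1, 1, 1, 1))$match)
  # PLC tie with strictly lower TRIO -> TRUE (PLC is inclusive)
  expect_true(match_experiment(row(1, 1, 0.5, 1))$match)
  # property: flipping the TRIO inequality flips the flag unless tied
  set.seed(33)
  for (i in 1:50) {
    v <- runif(4)
    m1 <- match_experiment(row(v[1], v[2], v[3], v[4]))$match
    m2 <- match_experiment(row(v[3], v[2], v[1], v[4]))$match
    plc_ok <- v[4] >= v[2]
    if (v[1] != v[3] && plc_ok) expect_false(m1 && m2)
    if (v[1] != v[3] && plc_ok) expect_true(m1 || m2)
  }
})

test_that("evaluate_batch preserves sampler metadata and counts exclusions", {
  batch <- sample_parameter_sets(default_ranges(), "lhs", n_base = 6,
                                 seed = 13)
  ev <- evaluate_batch(batch, params = gq_params("initial"))
  expect_equal(attr(ev, "scheme"), "lhs")
  expect_equal(attr(ev, "seed"), 13)
  expect_equal(attr(ev, "n_excluded"), 0)
  expect_s3_class(attr(ev, "ranges"), "gq_ranges")
})
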