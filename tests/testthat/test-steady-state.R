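test_that("reduced toy cycle matches its closed-form steady state", {
  fixtures <- list(
    make_toy_fixture(),
    make_toy_fixture(k_gef = 2, k_hyd = 0.1, k_at1 = 3, k_dt1 = 0.5,
                     k_trimer = 20, f_act = 0.05, TRIO_tot = 1.2),
    make_toy_fixture(k_gef = 0.5, f_act = 0.2, Gbg_tot = 2, Ga_tot = 0.8)
  )
  for (fx in fixtures) {
    res <- solve_steady_state(fx$params)
    expect_lt(max(rel_diff(res$state[res$state > 1e-14],
                           fx$closed_form[res$state > 1e-14])), 1e-8)
    expect_equal(res$active_TRIO, unname(fx$closed_form[["GT_TRIO_wt"]]),
                 tolerance = 1e-8)
  }
})

test_that("integration and root-finding agree across random parameter sets", {
  draws <- random_param_draws(30, seed = 42)
  for (i in seq_len(nrow(draws))) {
    p <- apply_row(gq_params("initial"), draws[i, ])
    a <- solve_steady_state(p, "GNAQ:Q209L:het", method = "ode")
    b <- solve_steady_state(p, "GNAQ:Q209L:het", method = "root")
    expect_true(a$converged && b$converged)
    expect_lt(rel_diff(a$active_TRIO, b$active_TRIO), 1e-6)
    expect_lt(rel_diff(a$active_PLC, b$active_PLC), 1e-6)
  }
})

test_that("conservation holds at steady state for all genotypes", {
  draws <- random_param_draws(8, seed = 7, params = gq_params("revised"))
  genos <- c("WT", "GNAQ:Q209L:het", "GNAQ:R183C:hom", "CYSLTR2:L129Q:het")
  for (i in seq_len(nrow(draws))) {
    p <- apply_row(gq_params("revised"), draws[i, ])
    for (g in genos) {
      res <- solve_steady_state(p, g)
      chk <- conservation_check(res$state, res$network)
      expect_lt(max(chk$rel_error), 1e-8)
      expect_true(all(res$state >= 0))
    }
  }
})

test_that("raising the WT receptor active fraction never lowers the readouts", {
  f_grid <- c(0.001, 0.005, 0.02, 0.1, 0.5, 1)
  res <- purrr::map_dfr(f_grid, function(f) {
    r <- solve_steady_state(gq_params("revised", f_act_wt = f), "WT")
    tibble::tibble(f = f, trio = r$active_TRIO, plc = r$active_PLC)
  })
  expect_true(all(diff(res$trio) >= -1e-12))
  expect_true(all(diff(res$plc) >= -1e-12))
})

test_that("initial preset reproduces the mutant activation panel", {
  p <- gq_params("initial")
  sim <- simulate_genotypes(
    p, c("GNAQ:Q209L:het", "GNAQ:Q209L:hom", "GNAQ:Q209P:het",
         "GNAQ:Q209P:hom", "GNAQ:R183C:het", "GNAQ:R183C:hom",
         "CYSLTR2:L129Q:het")
  )
  g <- function(x) sim[sim$genotype == x, ]
  wt <- g("WT")
  expect_gt(wt$active_TRIO, 0)   # small basal signal, not zero
  expect_gt(wt$active_PLC, 0)

  muts <- sim[sim$genotype != "WT", ]
  expect_true(all(muts$fold_TRIO > 1))
  expect_true(all(muts$fold_PLC > 1))

  # homozygous slightly above heterozygous for every G-alpha variant
  for (v in c("GNAQ:Q209L", "GNAQ:Q209P", "GNAQ:R183C")) {
    expect_gt(g(paste0(v, ":hom"))$fold_TRIO, g(paste0(v, ":het"))$fold_TRIO)
    expect_gt(g(paste0(v, ":hom"))$fold_PLC, g(paste0(v, ":het"))$fold_PLC)
  }

  # ordering: WT < R183C < Q209P ~ Q209L on fold_TRIO
  expect_lt(g("GNAQ:R183C:het")$fold_TRIO, g("GNAQ:Q209P:het")$fold_TRIO)
  expect_lt(g("GNAQ:R183C:het")$fold_TRIO, g("GNAQ:Q209L:het")$fold_TRIO)
  expect_lt(g("GNAQ:R183C:het")$fold_PLC, g("GNAQ:Q209L:het")$fold_PLC)
  expect_equal(g("GNAQ:Q209P:het")$fold_TRIO, g("GNAQ:Q209L:het")$fold_TRIO,
               tolerance = 0.3)

  # L129Q: near-complete loss of PLC-beta activation relative to Q209L
  excess <- (g("CYSLTR2:L129Q:het")$fold_PLC - 1) /
    (g("GNAQ:Q209L:het")$fold_PLC - 1)
  expect_lt(excess, 0.1)
  # ... while TRIO activation is only slightly-to-moderately weaker
  expect_gt(g("CYSLTR2:L129Q:het")$fold_TRIO, 1)
  expect_lt(g("CYSLTR2:L129Q:het")$fold_TRIO, g("GNAQ:Q209L:het")$fold_TRIO)
})

test_that("stimulated conditions raise WT signaling", {
  basal <- solve_steady_state(gq_params("initial"), "WT")
  stim <- solve_steady_state(gq_params("initial"), "WT", stimulated = TRUE)
  expect_gt(stim$active_TRIO, basal$active_TRIO)
  expect_gt(stim$active_PLC, basal$active_PLC)
})

test_that("fold changes behave as ratios with guarded baselines", {
  wt <- solve_steady_state(gq_params("revised"), "WT")
  expect_equal(as.numeric(fold_changes(wt, wt)), c(1, 1))
  broken <- wt
  broken$active_TRIO <- 0
  expect_error(fold_changes(wt, broken), "positive")
})

test_that("steady states are insensitive to the starting condition", {
  for (g in c("WT", "GNAQ:Q209L:het", "CYSLTR2:L129Q:het")) {
    res <- solve_steady_state(gq_params("revised"), g,
                              check_multistable = TRUE)
    expect_false(res$multistable)
  }
})

test_that("tidy and glance return well-formed tibbles", {
  res <- solve_steady_state(gq_params(), "GNAQ:Q209L:het")
  td <- tidy(res)
  expect_equal(nrow(td), 22)
  expect_named(td, c("species", "concentration"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$genotype, "GNAQ:Q209L:het")
})
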