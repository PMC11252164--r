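test_that("dose zero reproduces the drug-free steady state exactly", {
  p <- gq_params("revised")
  free <- solve_steady_state(p, "GNAQ:Q209L:het")
  with0 <- solve_steady_state(p, "GNAQ:Q209L:het", drug = gq_drug(),
                              dose = 0)
  expect_equal(with0$active_TRIO, free$active_TRIO, tolerance = 1e-10)
  expect_equal(with0$active_PLC, free$active_PLC, tolerance = 1e-10)
})

test_that("dose responses are monotone non-increasing for shipped genotypes", {
  p <- gq_params("revised")
  for (g in c("WT", "GNAQ:R183C:het", "GNAQ:Q209L:het")) {
    curve <- dose_response(p, g, grid = dose_grid(points = 13))
    expect_true(all(curve$converged))
    expect_true(all(diff(curve$active_TRIO) <= 1e-9))
    expect_true(all(diff(curve$active_PLC) <= 1e-9))
  }
})

test_that("G-alpha conservation includes drug-bound species at every dose", {
  p <- gq_params("revised")
  for (d in c(0, 1e-4, 0.01, 1)) {
    res <- solve_steady_state(p, "GNAQ:R183C:het", drug = gq_drug(),
                              dose = d)
    chk <- conservation_check(res$state, res$network)
    expect_lt(max(chk$rel_error), 1e-8)
    if (d >= 0.01) {
      expect_gt(sum(res$state[c("GDP_D_wt", "HT_D_wt")]), 0)
    }
  }
})

test_that("IC50 ordering shows the log-shift between GAP-sensitive and -insensitive mutants", {
  for (preset in c("initial", "revised")) {
    p <- gq_params(preset)
    ic <- vapply(c("WT", "GNAQ:R183C:het", "GNAQ:Q209L:het"), function(g) {
      glance(dose_response(p, g))$ic50_TRIO
    }, numeric(1))
    expect_true(all(is.finite(ic)))
    expect_lte(ic[["WT"]], ic[["GNAQ:R183C:het"]] * (1 + 1e-6))
    expect_lt(ic[["GNAQ:R183C:het"]], ic[["GNAQ:Q209L:het"]])
    ratio <- ic[["GNAQ:Q209L:het"]] / ic[["GNAQ:R183C:het"]]
    expect_gte(ratio, 5)
    expect_lte(ratio, 50)
  }
})

test_that("saturating GDI suppresses WT signaling but cannot trap a never-hydrolyzing mutant", {
  p <- gq_params("revised")
  drug <- gq_drug()
  sat <- 1e4 * drug$k_off / drug$k_on
  wt0 <- solve_steady_state(p, "WT")
  wt <- solve_steady_state(p, "WT", drug = drug, dose = sat)
  expect_lt(wt$active_TRIO, 0.01 * wt0$active_TRIO)
  expect_lt(wt$active_PLC, 0.01 * wt0$active_PLC)

  # exact zero hydrolysis: GTP-loaded mutant G-alpha never revisits the
  # GDP state, so the GDP-state drug cannot extinguish the mutant signal
  p0 <- set_params(p, `Q209L.r_hyd` = 0, `Q209L.r_gap` = 0)
  mut <- solve_steady_state(p0, "GNAQ:Q209L:het", drug = drug, dose = sat)
  mut0 <- solve_steady_state(p0, "GNAQ:Q209L:het")
  expect_gt(mut$active_TRIO, 0.5 * mut0$active_TRIO)
})

test_that("IC50 interpolation recovers a known midpoint and reports failures", {
  grid <- 10^seq(-3, 3, length.out = 25)
  hill <- function(d, mid) 1 / (1 + d / mid)
  for (mid in c(0.01, 1, 50)) {
    est <- estimate_ic50(grid, hill(grid, mid), baseline = 1)
    step <- grid[2] / grid[1]
    expect_lt(abs(log10(est) - log10(mid)), log10(step))
  }
  # constant curve: no 50% crossing -> failure status
  expect_true(is.na(estimate_ic50(grid, rep(1, 25), baseline = 1)))
  # non-monotone curve: first crossing used, warning logged
  wobble <- c(1, 0.9, 0.4, 0.7, 0.3, 0.1)
  expect_warning(
    est2 <- estimate_ic50(10^(0:5), wobble, baseline = 1),
    "non-monotone"
  )
  expect_lt(est2, 10^2.5)
})

test_that("dose-response curves flag non-convergent doses instead of failing", {
  curve <- dose_response(gq_params("revised"), "WT",
                         grid = dose_grid(points = 7))
  expect_s3_class(curve, "gq_dose_response")
  expect_true(all(c("dose", "active_TRIO", "active_PLC", "converged") %in%
                    names(curve)))
  expect_error(dose_response(gq_params(), "WT", grid = c(1, 1, 2)),
               "increasing")
})
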