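#' Sobol total sensitivity indices from a Saltelli batch
#'
#' Estimates the total-order index of every varied parameter for a scalar
#' model output using the Jansen estimator on the A / AB_i blocks of a
#' Saltelli design:
#' `ST_i = mean((f(A) - f(AB_i))^2) / (2 * Var(f))`,
#' with the output variance pooled over the A and B blocks. Confidence
#' intervals come from a bootstrap over the base-sample index.
#'
#' @param batch a `gq_batch` sampled with `scheme = "saltelli"`.
#' @param values numeric vector of model outputs, one per batch row
#'   (in batch row order). `NA` rows (excluded solves) propagate: base
#'   samples touching an `NA` are dropped from the estimator.
#' @param n_boot bootstrap replicates for the confidence interval.
#' @param conf confidence level.
#' @return tibble: `parameter`, `total_index`, `conf_low`, `conf_high`,
#'   `n_base_used`.
#' @export
sobol_total <- function(batch, values, n_boot = 200, conf = 0.95) {
  if (!identical(attr(batch, "scheme", exact = TRUE), "saltelli")) {
    stop("sobol_total() requires a batch sampled with the Saltelli scheme",
         call. = FALSE)
  }
  block <- attr(batch, "block", exact = TRUE)
  idx <- attr(batch, "base_index", exact = TRUE)
  ranges <- attr(batch, "ranges", exact = TRUE)
  stopifnot(length(values) == nrow(batch))
  d <- nrow(ranges)
  n_base <- attr(batch, "n_base", exact = TRUE)

  by_block <- function(bl) values[block == bl][order(idx[block == bl])]
  fA <- by_block("A")
  fB <- by_block("B")
  fAB <- lapply(seq_len(d), function(i) by_block(paste0("AB", i)))

  est_one <- function(i, rows) {
    ok <- is.finite(fA[rows]) & is.finite(fB[rows]) & is.finite(fAB[[i]][rows])
    a <- fA[rows][ok]; b <- fB[rows][ok]; ab <- fAB[[i]][rows][ok]
    v <- stats::var(c(a, b))
    if (!is.finite(v) || v <= 0) return(c(st = NA_real_, n = sum(ok)))
    c(st = mean((a - ab)^2) / (2 * v), n = sum(ok))
  }

  all_rows <- seq_len(n_base)
  purrr::map_dfr(seq_len(d), function(i) {
    point <- est_one(i, all_rows)
    boots <- replicate(n_boot, {
      est_one(i, sample(all_rows, replace = TRUE))[["st"]]
    })
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    tibble::tibble(
      parameter = ranges$name[i],
      total_index = point[["st"]],
      conf_low = qs[1], conf_high = qs[2],
      n_base_used = as.integer(point[["n"]])
    )
  })
}

#' First-order Sobol indices (Saltelli estimator)
#'
#' `S_i = (mean(f(B) * (f(AB_i) - f(A)))) / Var(f)`. Provided mainly so
#' the sum-of-first-order diagnostic is available; the headline analyses
#' use [sobol_total()].
#'
#' @inheritParams sobol_total
#' @return tibble: `parameter`, `first_order`.
#' @export
sobol_first <- function(batch, values) {
  if (!identical(attr(batch, "scheme", exact = TRUE), "saltelli")) {
    stop("sobol_first() requires a Saltelli batch", call. = FALSE)
  }
  block <- attr(batch, "block", exact = TRUE)
  idx <- attr(batch, "base_index", exact = TRUE)
  ranges <- attr(batch, "ranges", exact = TRUE)
  d <- nrow(ranges)
  by_block <- function(bl) values[block == bl][order(idx[block == bl])]
  fA <- by_block("A"); fB <- by_block("B")
  purrr::map_dfr(seq_len(d), function(i) {
    fAB <- by_block(paste0("AB", i))
    ok <- is.finite(fA) & is.finite(fB) & is.finite(fAB)
    v <- stats::var(c(fA[ok], fB[ok]))
    tibble::tibble(parameter = ranges$name[i],
                   first_order = mean(fB[ok] * (fAB[ok] - fA[ok])) / v)
  })
}

#' Sobol sensitivity of the Q209L-vs-L129Q output differences
#'
#' Convenience pipeline for the headline global sensitivity analysis:
#' samples a Saltelli batch over `ranges`, evaluates the model for the
#' heterozygous Q209L and L129Q genotypes at every set, and computes the
#' total index of every varied parameter for the two difference outputs
#' `delta_TRIO = active_TRIO(Q209L) - active_TRIO(L129Q)` and
#' `delta_PLC = active_PLC(Q209L) - active_PLC(L129Q)`.
#'
#' @param ranges a [param_ranges()] tibble; [default_ranges()] by default.
#' @param params fixed parameters for the unsampled symbols.
#' @param n_base Saltelli base sample size.
#' @param seed integer seed.
#' @param n_boot bootstrap replicates for the CIs.
#' @return an object of class `gq_sensitivity`: tibble with `output`
#'   (`delta_TRIO` / `delta_PLC`), `parameter`, `total_index`, CI bounds;
#'   the evaluated batch is attached as attribute `batch`.
#' @export
sensitivity_analysis <- function(ranges = default_ranges(),
                                 params = gq_params("initial"),
                                 n_base = 128, seed = 1, n_boot = 200) {
  batch <- sample_parameter_sets(ranges, scheme = "saltelli",
                                 n_base = n_base, seed = seed)
  ev <- evaluate_batch(batch, params = params, include_wt = FALSE)
  keep <- ev$converged
  d_trio <- ifelse(keep, ev$trio_q209l - ev$trio_l129q, NA_real_)
  d_plc <- ifelse(keep, ev$plc_q209l - ev$plc_l129q, NA_real_)
  res <- dplyr::bind_rows(
    dplyr::mutate(sobol_total(ev, d_trio, n_boot = n_boot),
                  output = "delta_TRIO", .before = 1),
    dplyr::mutate(sobol_total(ev, d_plc, n_boot = n_boot),
                  output = "delta_PLC", .before = 1)
  )
  structure(res, class = c("gq_sensitivity", class(res)), batch = ev)
}

#' Plot Sobol total indices
#'
#' @param object a `gq_sensitivity` result.
#' @param ... unused.
#' @return a ggplot bar chart with bootstrap intervals, one facet per
#'   output.
#' @method autoplot gq_sensitivity
#' @export
autoplot.gq_sensitivity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$parameter, .data$total_index),
    y = .data$total_index
  )) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(x = NULL, y = "Sobol total sensitivity index") +
    ggplot2::theme_minimal()
}
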