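#' Kolmogorov-Smirnov discrimination of match vs non-match sets
#'
#' For each named parameter, compares its sampled values between the
#' experiment-matching and non-matching classes with a two-sample KS test
#' and ranks parameters by the D statistic. P-values are
#' Benjamini-Hochberg adjusted across the scanned parameters.
#'
#' @param batch an evaluated batch carrying a `match` column (see
#'   [match_experiment()]); rows with `NA` match are dropped.
#' @param parameters character vector of columns to scan; defaults to the
#'   varied parameters recorded in the batch ranges.
#' @return tibble sorted by decreasing `D`: `parameter`, `D`, `p_value`,
#'   `p_adj`, `rank`.
#' @export
ks_discriminate <- function(batch, parameters = NULL) {
  if (!"match" %in% names(batch)) batch <- match_experiment(batch)
  if (is.null(parameters)) {
    ranges <- attr(batch, "ranges", exact = TRUE)
    if (is.null(ranges)) {
      stop("no `parameters` given and the batch has no range metadata",
           call. = FALSE)
    }
    parameters <- ranges$name
  }
  keep <- !is.na(batch$match)
  m <- batch$match[keep]
  if (!any(m) || all(m)) {
    stop("both match classes must be non-empty for KS discrimination",
         call. = FALSE)
  }
  if (min(sum(m), sum(!m)) < 10) {
    warning("a match class has fewer than 10 members; KS statistics are ",
            "unstable", call. = FALSE)
  }
  res <- purrr::map_dfr(parameters, function(pm) {
    x <- batch[[pm]][keep]
    kt <- suppressWarnings(stats::ks.test(x[m], x[!m]))
    tibble::tibble(parameter = pm, D = unname(kt$statistic),
                   p_value = kt$p.value)
  })
  res |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(dplyr::desc(.data$D)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' ROC curve for a single-parameter match classifier
#'
#' Sweeps a threshold over the sampled range of one parameter and treats
#' "predicted match" as the parameter being on the stated side of the
#' threshold: `direction = "ge"` predicts a match when the value is at or
#' above the threshold (the effector-bias convention), `direction = "lt"`
#' when it is below (the GAP-rate convention). Reports TPR/FPR at every
#' distinct threshold and the trapezoidal AUC.
#'
#' @param batch an evaluated batch with a `match` column.
#' @param parameter column name of the classifier parameter.
#' @param direction `"ge"` or `"lt"`.
#' @return an object of class `gq_roc`: tibble (`threshold`, `tpr`,
#'   `fpr`) with attributes `auc`, `parameter`, `direction`.
#' @export
roc_classifier <- function(batch, parameter, direction = c("ge", "lt")) {
  direction <- match.arg(direction)
  if (!"match" %in% names(batch)) batch <- match_experiment(batch)
  keep <- !is.na(batch$match)
  y <- batch$match[keep]
  x <- batch[[parameter]][keep]
  if (!any(y) || all(y)) {
    stop("both match classes must be non-empty for a ROC analysis",
         call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(x)), Inf)
  curve <- purrr::map_dfr(thr, function(t) {
    pred <- if (direction == "ge") x >= t else x < t
    tibble::tibble(threshold = t,
                   tpr = sum(pred & y) / sum(y),
                   fpr = sum(pred & !y) / sum(!y))
  }) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(curve, class = c("gq_roc", class(curve)),
            auc = auc, parameter = parameter, direction = direction)
}

#' @export
print.gq_roc <- function(x, ...) {
  cat("<gq_roc> parameter:", attr(x, "parameter"),
      " direction:", attr(x, "direction"),
      " AUC:", format(attr(x, "auc"), digits = 4), "\n")
  invisible(x)
}

#' One-row ROC summary
#'
#' @param x a `gq_roc` object.
#' @param ... unused.
#' @return one-row tibble: parameter, direction, AUC, n thresholds.
#' @method glance gq_roc
#' @export
glance.gq_roc <- function(x, ...) {
  tibble::tibble(parameter = attr(x, "parameter"),
                 direction = attr(x, "direction"),
                 auc = attr(x, "auc"),
                 n_thresholds = nrow(x))
}

#' Plot a ROC curve
#'
#' @param object a `gq_roc` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gq_roc
#' @export
autoplot.gq_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%s (AUC = %.3f)", attr(object, "parameter"),
                      attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Sweep the PLC-beta GAP rate
#'
#' Solves the steady state of each genotype over a grid of
#' `k_hyd2 / k_hyd` ratios with everything else fixed (the effector bias
#' stays at the preset value, 4 under the revised preset) and annotates
#' each grid point with the experiment-match flag of the Q209L-vs-L129Q
#' comparison.
#'
#' @param params a [gq_params()] object (revised preset by default, which
#'   fixes `r_at2 / r_at1 = 4`).
#' @param ratio_grid ascending grid of `k_hyd2 / k_hyd` fold values.
#' @param genotypes genotype strings to sweep.
#' @return an object of class `gq_sweep`: tibble (`ratio`, `genotype`,
#'   `active_TRIO`, `active_PLC`, `match`); `match` is the per-ratio flag,
#'   repeated across genotypes.
#' @export
khyd2_sweep <- function(params = gq_params("revised"),
                        ratio_grid = 10^seq(-0.5, 3, length.out = 25),
                        genotypes = c("WT", "GNAQ:Q209L:het",
                                      "CYSLTR2:L129Q:het")) {
  k_hyd <- params$kinetics[["k_hyd"]]
  rows <- purrr::map_dfr(ratio_grid, function(r) {
    p <- set_params(params, k_hyd2 = r * k_hyd)
    res <- purrr::map(genotypes, ~ solve_steady_state(p, .x))
    readout <- purrr::map2_dfr(res, genotypes, function(s, g) {
      tibble::tibble(ratio = r, genotype = g,
                     active_TRIO = s$active_TRIO,
                     active_PLC = s$active_PLC)
    })
    names(res) <- genotypes
    q <- res[["GNAQ:Q209L:het"]]; l <- res[["CYSLTR2:L129Q:het"]]
    m <- if (!is.null(q) && !is.null(l)) {
      l$active_PLC >= q$active_PLC && l$active_TRIO < q$active_TRIO
    } else NA
    dplyr::mutate(readout, match = m)
  })
  structure(rows, class = c("gq_sweep", class(rows)))
}

#' Plot a GAP-rate sweep
#'
#' @param object a `gq_sweep` result.
#' @param ... unused.
#' @return a ggplot object: readouts vs `k_hyd2 / k_hyd`, one facet per
#'   readout, with the experiment-matching region shaded.
#' @method autoplot gq_sweep
#' @export
autoplot.gq_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("active_TRIO", "active_PLC"),
                        names_to = "readout", values_to = "level")
  shade <- df |>
    dplyr::filter(.data$match) |>
    dplyr::summarise(xmin = min(.data$ratio), xmax = max(.data$ratio))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$ratio, .data$level,
                                        colour = .data$genotype))
  if (nrow(shade) == 1 && is.finite(shade$xmin)) {
    p <- p + ggplot2::annotate("rect", xmin = shade$xmin, xmax = shade$xmax,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "pink")
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(x = "k_hyd2 / k_hyd (fold over basal hydrolysis)",
                  y = "steady-state active effector") +
    ggplot2::theme_minimal()
}
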