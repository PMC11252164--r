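#' Guanine-nucleotide dissociation inhibitor (GDI) parameters
#'
#' An FR900359/YM-254890-type inhibitor that reversibly binds and
#' sequesters GDP-bound G-alpha. By default the drug binds both the free
#' GaGDP subunit and the GaGDP-Gbg heterotrimer (the GDI stabilizes the
#' GDP state generically); restricting `targets` to `"free_GaGDP"` probes
#' the mechanism. The drug has equal affinity for the WT and mutant pools
#' and its concentration is clamped (buffered bath), so dose is a
#' parameter, not a conserved species.
#'
#' @param k_on association rate constant (per concentration per time).
#' @param k_off dissociation rate constant (per time).
#' @param targets subset of `c("free_GaGDP", "heterotrimer")`.
#' @return an object of class `gq_drug`.
#' @examples
#' d <- gq_drug()
#' d$k_off / d$k_on  # dissociation constant
#' @export
gq_drug <- function(k_on = 10, k_off = 0.01,
                    targets = c("free_GaGDP", "heterotrimer")) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (k_on < 0 || k_off < 0) {
    stop("drug rate constants must be nonnegative", call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off, targets = targets),
            class = "gq_drug")
}

#' Default log-spaced dose grid
#'
#' @param drug a [gq_drug()]; the grid is centered on its dissociation
#'   constant `k_off / k_on`.
#' @param decades total width of the grid in decades.
#' @param points number of grid points.
#' @return strictly increasing numeric vector of doses.
#' @export
dose_grid <- function(drug = gq_drug(), decades = 6, points = 25) {
  kd <- drug$k_off / drug$k_on
  10^seq(log10(kd) - decades / 2, log10(kd) + decades / 2,
         length.out = points)
}

#' GDI dose-response curve
#'
#' Solves the steady state of the drug-extended network at each dose and
#' reports the active-TRIO/active-PLC readouts. Doses at which the solver
#' fails to converge are kept in the grid with `NA` readouts (the curve is
#' returned with gaps rather than failing wholesale).
#'
#' @param params a [gq_params()] object.
#' @param genotype genotype string or [gq_genotype()].
#' @param drug a [gq_drug()].
#' @param grid ascending dose vector; default [dose_grid()] (25 points
#'   over 6 decades around the drug Kd).
#' @param ... passed to [solve_steady_state()].
#' @return an object of class `gq_dose_response`: a tibble (`dose`,
#'   `active_TRIO`, `active_PLC`, `converged`) with attributes `baseline`
#'   (drug-free `gq_steady`), `ic50_TRIO`, `ic50_PLC`, `genotype`.
#' @export
dose_response <- function(params, genotype = "WT", drug = gq_drug(),
                          grid = dose_grid(drug), ...) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("dose grid must be strictly increasing", call. = FALSE)
  }
  baseline <- solve_steady_state(params, genotype, drug = drug, dose = 0, ...)
  rows <- purrr::map_dfr(grid, function(d) {
    res <- solve_steady_state(params, genotype, drug = drug, dose = d,
                              must_converge = FALSE, ...)
    tibble::tibble(
      dose = d,
      active_TRIO = if (res$converged) res$active_TRIO else NA_real_,
      active_PLC = if (res$converged) res$active_PLC else NA_real_,
      converged = res$converged
    )
  })
  structure(
    rows,
    class = c("gq_dose_response", class(rows)),
    baseline = baseline,
    genotype = format(parse_genotype(genotype)),
    ic50_TRIO = estimate_ic50(grid, rows$active_TRIO, baseline$active_TRIO),
    ic50_PLC = estimate_ic50(grid, rows$active_PLC, baseline$active_PLC)
  )
}

#' IC50 by log-linear interpolation
#'
#' The dose at which a readout crosses half of its drug-free baseline,
#' log-linearly interpolated between the bracketing grid points. If the
#' curve never reaches 50% inhibition the estimate is `NA` (failure
#' status). If a non-monotone segment produces several crossings, the
#' first is used and a warning is logged.
#'
#' @param dose ascending dose vector.
#' @param readout readout at each dose (`NA` allowed for gaps).
#' @param baseline drug-free readout.
#' @return the IC50 (same units as `dose`) or `NA_real_`.
#' @export
estimate_ic50 <- function(dose, readout, baseline) {
  stopifnot(length(dose) == length(readout), baseline >= 0)
  keep <- is.finite(readout)
  dose <- dose[keep]; readout <- readout[keep]
  if (length(dose) < 2 || baseline <= 0) return(NA_real_)
  half <- baseline / 2
  below <- readout <= half
  if (!any(below)) return(NA_real_)
  crossings <- which(diff(below) == 1L)
  if (below[1]) crossings <- c(0L, crossings)
  if (length(crossings) > 1) {
    warning("non-monotone dose-response: multiple 50% crossings; ",
            "using the first", call. = FALSE)
  }
  i <- crossings[1]
  if (i == 0L) return(dose[1])
  # log-linear interpolation between (dose[i], readout[i]) and the next point
  f <- (readout[i] - half) / (readout[i] - readout[i + 1])
  10^(log10(dose[i]) + f * (log10(dose[i + 1]) - log10(dose[i])))
}

#' IC50 summary of a dose-response curve
#'
#' @param x a `gq_dose_response` object.
#' @param ... unused.
#' @return one-row tibble: genotype, baseline readouts, IC50s.
#' @method glance gq_dose_response
#' @export
glance.gq_dose_response <- function(x, ...) {
  base <- attr(x, "baseline")
  tibble::tibble(
    genotype = attr(x, "genotype"),
    baseline_TRIO = base$active_TRIO,
    baseline_PLC = base$active_PLC,
    ic50_TRIO = attr(x, "ic50_TRIO"),
    ic50_PLC = attr(x, "ic50_PLC")
  )
}

#' Plot a dose-response curve
#'
#' @param object a `gq_dose_response` object.
#' @param ... unused.
#' @return a ggplot object: both readouts, normalized to their drug-free
#'   baseline, on a log dose axis.
#' @method autoplot gq_dose_response
#' @export
autoplot.gq_dose_response <- function(object, ...) {
  base <- attr(object, "baseline")
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      TRIO = .data$active_TRIO / base$active_TRIO,
      `PLC-beta` = .data$active_PLC / base$active_PLC
    ) |>
    tidyr::pivot_longer(c("TRIO", "PLC-beta"), names_to = "readout",
                        values_to = "fraction_of_baseline")
  ggplot2::ggplot(df, ggplot2::aes(.data$dose, .data$fraction_of_baseline,
                                   colour = .data$readout)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "GDI dose", y = "active effector (fraction of baseline)",
                  title = attr(object, "genotype")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
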