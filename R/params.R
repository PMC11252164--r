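#' Model parameters for the G-protein activation cycle
#'
#' Construct the full symbol table of the model: kinetic rate constants,
#' total protein abundances, receptor activity fractions, and per-variant
#' mutant scaling bundles. Two named presets are shipped:
#'
#' * `"initial"` — the first-pass parameterization in which PLC-beta is a
#'   very strong GAP (`k_hyd2 / k_hyd = 770`) and the Q209L mutant binds
#'   both effectors like wild type (`r_at2 / r_at1 = 1`).
#' * `"revised"` — the updated parameterization with a TRIO-ward
#'   effector-binding bias for the Q209 mutants (the mutant-over-WT TRIO
#'   association is four times the mutant-over-WT PLC-beta association;
#'   see [effector_bias()]) and a milder PLC-beta GAP activity
#'   (`k_hyd2 / k_hyd = 20`, the log-midpoint of the accepted 1-40 band).
#'
#' Concentrations are nondimensionalized so that `Ga_tot = 1`; all other
#' abundances are relative to the total G-alpha pool. Rates are per second
#' (first order) or per concentration per second (second order). Fold-change
#' readouts are invariant to this scale choice. Exact literature values for
#' every constant are not pinned by the model's qualitative claims; the
#' shipped values are round, literature-scale magnitudes and every one can
#' be overridden here or from a config file (see [load_config()]).
#'
#' @param preset `"revised"` (default) or `"initial"`.
#' @param ... named overrides. Scalar symbols (e.g. `k_hyd2 = 0.1`,
#'   `TRIO_tot = 2`) replace the preset value; `variants` may be given as a
#'   list to replace whole scaling bundles.
#' @return An object of class `gq_params`: a list with elements
#'   `kinetics` (named numeric vector of the 13 shared rate constants),
#'   `totals` (6 protein abundances), `f_act_wt`, `stimulated_f_act`,
#'   `variants` (per-variant scaling bundles), and `preset`.
#' @examples
#' p <- gq_params("initial")
#' p$kinetics[["k_hyd2"]] / p$kinetics[["k_hyd"]]  # ~770
#' @export
gq_params <- function(preset = c("revised", "initial"), ...) {
  preset <- match.arg(preset)

  kinetics <- c(
    k_gef     = 1.2,
    k_hyd     = 0.013,
    k_rgs_on  = 30,
    k_rgs_off = 100,
    k_rgs_cat = 30,
    k_at1     = 10,
    k_dt1     = 1,
    k_at2     = 0.2,
    k_dt2     = 1,
    k_hyd2    = if (preset == "initial") 770 * 0.013 else 20 * 0.013,
    k_gtp_off = 0.001,
    k_nt_load = 100,
    k_trimer  = 100
  )

  totals <- c(
    R_tot    = 1,
    Ga_tot   = 1,
    Gbg_tot  = 1,
    RGS_tot  = 2,
    TRIO_tot = 0.5,
    PLC_tot  = 0.5
  )

  # revised preset: elevated mutant TRIO association (effector bias 4)
  q209_bias <- if (preset == "initial") 1 else 4
  variants <- list(
    Q209L = list(r_at1 = q209_bias, r_at2 = 1, r_hyd = 0.001, r_gap = 0.001),
    Q209P = list(r_at1 = q209_bias, r_at2 = 1, r_hyd = 0.002, r_gap = 0.002),
    R183C = list(r_at1 = 1, r_at2 = 1, r_hyd = 0.05, r_gap = 0.2),
    L129Q = list(r_at1 = 1, r_at2 = 1, r_hyd = 1, r_gap = 1, f_act_mut = 1)
  )

  p <- structure(
    list(
      kinetics = kinetics,
      totals = totals,
      f_act_wt = 0.01,
      stimulated_f_act = 1,
      variants = variants,
      preset = preset
    ),
    class = "gq_params"
  )
  p <- set_params(p, ...)
  validate_params(p)
  p
}

#' Override parameter values
#'
#' @param params a [gq_params()] object.
#' @param ... named scalar overrides (kinetic constant, abundance,
#'   `f_act_wt`, `stimulated_f_act`), or `variants = list(...)` to merge
#'   variant scaling bundles. Dotted names such as `Q209L.r_at2` address a
#'   single variant scaling.
#' @return the modified `gq_params` object (re-validated).
#' @export
set_params <- function(params, ...) {
  dots <- list(...)
  if (length(dots) == 0) return(params)
  nm <- names(dots)
  if (is.null(nm) || any(nm == "")) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  for (i in seq_along(dots)) {
    key <- nm[i]
    val <- dots[[i]]
    if (key == "variants") {
      for (v in names(val)) {
        if (!v %in% names(params$variants)) {
          stop("unknown variant in override: ", v, call. = FALSE)
        }
        params$variants[[v]] <- utils::modifyList(params$variants[[v]], val[[v]])
      }
    } else if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !parts[1] %in% names(params$variants)) {
        stop("unknown parameter symbol: ", key, call. = FALSE)
      }
      params$variants[[parts[1]]][[parts[2]]] <- val
    } else if (key %in% names(params$kinetics)) {
      params$kinetics[[key]] <- val
    } else if (key %in% names(params$totals)) {
      params$totals[[key]] <- val
    } else if (key %in% c("f_act_wt", "stimulated_f_act")) {
      params[[key]] <- val
    } else {
      stop("unknown parameter symbol: ", key, call. = FALSE)
    }
  }
  validate_params(params)
  params
}

#' @keywords internal
validate_params <- function(params) {
  stopifnot(inherits(params, "gq_params"))
  num <- c(params$kinetics, params$totals)
  bad <- names(num)[!is.finite(num) | num < 0]
  if (length(bad) > 0) {
    stop("parameter(s) must be finite and nonnegative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (f in c("f_act_wt", "stimulated_f_act")) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop(f, " must be a single value in [0, 1]", call. = FALSE)
    }
  }
  for (v in names(params$variants)) {
    b <- params$variants[[v]]
    for (r in intersect(names(b), c("r_at1", "r_at2", "r_hyd", "r_gap"))) {
      if (b[[r]] < 0) stop("variant ", v, ": ", r, " must be nonnegative",
                           call. = FALSE)
    }
    if (!is.null(b$f_act_mut) && (b$f_act_mut < 0 || b$f_act_mut > 1)) {
      stop("variant ", v, ": f_act_mut must be in [0, 1]", call. = FALSE)
    }
  }
  invisible(params)
}

#' @export
print.gq_params <- function(x, ...) {
  cat("<gq_params> preset:", x$preset, "\n")
  cat("  kinetics: ", paste(names(x$kinetics), signif(x$kinetics, 4),
                            sep = "=", collapse = ", "), "\n")
  cat("  totals:   ", paste(names(x$totals), signif(x$totals, 4),
                            sep = "=", collapse = ", "), "\n")
  cat("  f_act_wt:", x$f_act_wt,
      " stimulated_f_act:", x$stimulated_f_act, "\n")
  cat("  variants:", paste(names(x$variants), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten parameters to a single named numeric vector
#'
#' Used when echoing a fully resolved configuration into run manifests and
#' when writing parameter files. Variant scalings get dotted names
#' (`Q209L.r_at2`).
#'
#' @param params a [gq_params()] object.
#' @return named numeric vector.
#' @export
flatten_params <- function(params) {
  out <- c(params$kinetics, params$totals,
           f_act_wt = params$f_act_wt,
           stimulated_f_act = params$stimulated_f_act)
  for (v in names(params$variants)) {
    b <- unlist(params$variants[[v]])
    names(b) <- paste(v, names(b), sep = ".")
    out <- c(out, b)
  }
  out
}

#' Mutant effector-association bias of a parameter set
#'
#' The ratio of the Q209L mutant-over-WT TRIO association scaling to its
#' mutant-over-WT PLC-beta association scaling (`r_at1 / r_at2`). A value
#' above 1 means the mutant prefers TRIO over PLC-beta relative to WT
#' G-alpha, the direction co-immunoprecipitation data support; the revised
#' preset sets it to 4. This composite is the quantity swept as a
#' match-experiment classifier in the global analyses.
#'
#' @param params a [gq_params()] object.
#' @param variant which mutant bundle to read (default `"Q209L"`).
#' @return a single number.
#' @export
effector_bias <- function(params, variant = "Q209L") {
  b <- params$variants[[variant]]
  b$r_at1 / b$r_at2
}
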