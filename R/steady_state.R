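#' Solve the dynamic equilibrium of the activation cycle
#'
#' Integrates the mass-action ODE system with a stiff solver (deSolve's
#' `lsoda`, compiled right-hand side) from the canonical initial condition
#' (all G-alpha in heterotrimer, all effectors/RGS free) until the maximum
#' time derivative falls below tolerance, optionally followed by a
#' Levenberg-Marquardt root-find refinement on the full system augmented
#' with the conservation constraints (`method = "root"`).
#'
#' @param params a [gq_params()] object.
#' @param genotype a [gq_genotype()] or genotype string (default all-WT).
#' @param method `"ode"` (integrate to equilibrium, default) or `"root"`
#'   (integrate briefly, then polish by root finding). Both routes must and
#'   do agree on the readouts; the dual route exists as a numerical check.
#' @param drug,dose optional [gq_drug()] and clamped dose (see
#'   [dose_response()]).
#' @param stimulated simulate ligand-stimulated conditions (WT receptor
#'   active fraction raised to `stimulated_f_act`).
#' @param atol absolute tolerance on `max |d/dt|` at the returned state;
#'   default `1e-10 *` the largest protein abundance.
#' @param must_converge if `TRUE` (default) a non-converged solve is an
#'   error; if `FALSE` the result is returned with `converged = FALSE`.
#' @param check_multistable if `TRUE`, re-solve from a second initial
#'   condition (all G-alpha dissociated as free GaGDP) and flag the
#'   parameter set as multistable when the readouts disagree by more than
#'   `1e-4` relative.
#' @return An object of class `gq_steady`: the converged `state`, the
#'   readouts `active_TRIO` (sum of GaGTP-TRIO complexes over both pools)
#'   and `active_PLC`, `residual_norm`, `converged`, `multistable`, and the
#'   underlying `network`.
#' @examples
#' \donttest{
#' wt <- solve_steady_state(gq_params("initial"))
#' mut <- solve_steady_state(gq_params("initial"), "GNAQ:Q209L:het")
#' fold_changes(mut, wt)
#' }
#' @export
solve_steady_state <- function(params, genotype = "WT",
                               method = c("ode", "root"),
                               drug = NULL, dose = 0, stimulated = FALSE,
                               atol = NULL, must_converge = TRUE,
                               check_multistable = FALSE) {
  method <- match.arg(method)
  network <- build_network(params, genotype, drug = drug, dose = dose,
                           stimulated = stimulated)
  if (is.null(atol)) atol <- 1e-10 * max(params$totals)

  res <- .steady_from(network$y0, network, method, atol)
  multistable <- FALSE
  if (check_multistable) {
    alt <- .alt_initial_state(network)
    res2 <- .steady_from(alt, network, method, atol)
    if (res$converged && res2$converged) {
      rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
      if (rel(res$active_TRIO, res2$active_TRIO) > 1e-4 ||
          rel(res$active_PLC, res2$active_PLC) > 1e-4) {
        multistable <- TRUE
        warning("steady state depends on the initial condition; ",
                "parameter set flagged as multistable", call. = FALSE)
      }
    }
  }
  if (!res$converged && must_converge) {
    stop("steady-state solve did not converge (residual ",
         format(res$residual_norm), " > ", format(atol), ")", call. = FALSE)
  }
  structure(
    list(state = res$state, active_TRIO = res$active_TRIO,
         active_PLC = res$active_PLC, residual_norm = res$residual_norm,
         converged = res$converged, multistable = multistable,
         method = method, network = network),
    class = "gq_steady"
  )
}

# all-dissociated alternative initial condition (multistability probe)
.alt_initial_state <- function(network) {
  y <- network$y0
  y[] <- 0
  y[["GDP_wt"]] <- network$conservation$Ga_wt$total
  y[["GDP_mut"]] <- network$conservation$Ga_mut$total
  y[["Gbg"]] <- network$conservation$Gbg$total
  y[["TRIO"]] <- network$conservation$TRIO$total
  y[["PLC"]] <- network$conservation$PLC$total
  y[["RGS"]] <- network$conservation$RGS$total
  y
}

.residual_norm <- function(y, network) {
  max(abs(gq_rhs(y, network)))
}

.steady_from <- function(y0, network, method, atol) {
  horizons <- c(1e6, 1e8, 1e10)
  if (method == "root") horizons <- 1e4
  y <- as.numeric(y0)
  converged <- FALSE
  for (t_end in horizons) {
    out <- try(deSolve::lsoda(
      y = y, times = c(0, t_end), func = "gq_derivs",
      parms = network$parms, dllname = "gqcycle", initfunc = "gq_initmod",
      rtol = 1e-10, atol = 1e-14, maxsteps = 50000
    ), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < 2) break
    y <- out[nrow(out), -1]
    if (method == "ode" && .residual_norm(y, network) <= atol) {
      converged <- TRUE
      break
    }
  }
  if (method == "root") {
    y <- .root_polish(y, network)
    converged <- .residual_norm(y, network) <= atol
  } else if (!converged) {
    # one last polish attempt before declaring failure
    y <- .root_polish(y, network)
    converged <- .residual_norm(y, network) <= atol
  }
  scale <- max(network$params$totals)
  if (any(y < -1e-12 * scale)) converged <- FALSE
  y <- pmax(y, 0)
  y <- stats::setNames(as.numeric(y), network$species)
  list(
    state = y,
    active_TRIO = unname(y[["GT_TRIO_wt"]] + y[["GT_TRIO_mut"]]),
    active_PLC = unname(y[["GT_PLC_wt"]] + y[["GT_PLC_mut"]]),
    residual_norm = .residual_norm(y, network),
    converged = converged
  )
}

# Levenberg-Marquardt refinement on rhs = 0 plus the conservation
# constraints (the constraints pin the singular directions of the
# mass-action Jacobian).
.root_polish <- function(y, network) {
  resid <- function(x) {
    r <- as.numeric(gq_rhs(x, network))
    cons <- vapply(network$conservation,
                   function(g) sum(x[g$idx]) - g$total, numeric(1))
    c(r, cons)
  }
  fit <- try(minpack.lm::nls.lm(
    par = pmax(as.numeric(y), 0), fn = resid,
    lower = rep(0, length(y)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         xtol = 1e-15)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(y)
  cand <- fit$par
  if (.residual_norm(cand, network) <= .residual_norm(y, network)) cand else y
}

#' Fold changes of the active-effector readouts
#'
#' Ratio of a result's readouts to an all-WT baseline computed under
#' identical parameters; the fold change in activation relative to WT is
#' the model's measure of pathway activation.
#'
#' @param result,baseline `gq_steady` objects.
#' @return tibble with `fold_TRIO` and `fold_PLC`.
#' @export
fold_changes <- function(result, baseline) {
  stopifnot(inherits(result, "gq_steady"), inherits(baseline, "gq_steady"))
  if (baseline$active_TRIO <= 0 || baseline$active_PLC <= 0) {
    stop("baseline readouts must be positive to form fold changes",
         call. = FALSE)
  }
  tibble::tibble(
    fold_TRIO = result$active_TRIO / baseline$active_TRIO,
    fold_PLC = result$active_PLC / baseline$active_PLC
  )
}

#' Simulate a panel of genotypes against their WT baseline
#'
#' @param params a [gq_params()] object.
#' @param genotypes character vector of genotype strings (WT is always
#'   solved as the baseline and included as the first row).
#' @param stimulated simulate stimulated conditions for every genotype.
#' @param ... passed to [solve_steady_state()].
#' @return tibble: one row per genotype with `active_TRIO`, `active_PLC`,
#'   `fold_TRIO`, `fold_PLC`, `residual_norm`.
#' @export
simulate_genotypes <- function(params,
                               genotypes = c("GNAQ:Q209L:het",
                                             "GNAQ:Q209P:het",
                                             "GNAQ:R183C:het",
                                             "CYSLTR2:L129Q:het"),
                               stimulated = FALSE, ...) {
  base <- solve_steady_state(params, "WT", stimulated = stimulated, ...)
  rows <- purrr::map_dfr(c("WT", genotypes), function(gstr) {
    res <- if (gstr == "WT") base
           else solve_steady_state(params, gstr, stimulated = stimulated, ...)
    dplyr::bind_cols(
      tibble::tibble(genotype = gstr,
                     active_TRIO = res$active_TRIO,
                     active_PLC = res$active_PLC),
      fold_changes(res, base),
      tibble::tibble(residual_norm = res$residual_norm)
    )
  })
  rows
}

#' @export
print.gq_steady <- function(x, ...) {
  cat("<gq_steady>", format(x$network$genotype),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  cat("  active_TRIO:", format(x$active_TRIO, digits = 6),
      " active_PLC:", format(x$active_PLC, digits = 6), "\n")
  cat("  residual_norm:", format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

#' Tidy a steady-state result into a species table
#'
#' @param x a `gq_steady` object.
#' @param ... unused.
#' @return tibble with `species` and `concentration`.
#' @method tidy gq_steady
#' @export
tidy.gq_steady <- function(x, ...) {
  tibble::tibble(species = names(x$state),
                 concentration = as.numeric(x$state))
}

#' One-row summary of a steady-state result
#'
#' @param x a `gq_steady` object.
#' @param ... unused.
#' @return one-row tibble: genotype, readouts, residual, convergence flag.
#' @method glance gq_steady
#' @export
glance.gq_steady <- function(x, ...) {
  tibble::tibble(
    genotype = format(x$network$genotype),
    active_TRIO = x$active_TRIO,
    active_PLC = x$active_PLC,
    residual_norm = x$residual_norm,
    converged = x$converged,
    multistable = x$multistable
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
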