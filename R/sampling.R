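#' Parameter range specification
#'
#' Ranges for the globally varied parameters. Each varied symbol gets a
#' lower/upper bound and a sampling scale (`"log"` for log-uniform,
#' `"uniform"` for uniform). Symbols must be model parameter names, the
#' composite `effector_bias` (the Q209L mutant TRIO-over-PLC-beta
#' association bias, sampled by moving the mutant TRIO association rate
#' constant with the dissociation rates and the mutant PLC-beta scaling
#' held fixed; see [effector_bias()]), or names beginning with `dummy`
#' (inert columns used to calibrate sensitivity estimates).
#'
#' @param name character vector of varied symbols.
#' @param lower,upper numeric bounds (positive when `scale = "log"`).
#' @param scale `"log"` or `"uniform"`, recycled.
#' @return a tibble of class `gq_ranges`.
#' @seealso [default_ranges()]
#' @export
param_ranges <- function(name, lower, upper, scale = "log") {
  stopifnot(length(name) > 0, length(lower) == length(name),
            length(upper) == length(name))
  scale <- rep_len(match.arg(scale, c("log", "uniform"), several.ok = TRUE),
                   length(name))
  if (any(lower >= upper)) stop("lower must be < upper", call. = FALSE)
  if (any(scale == "log" & lower <= 0)) {
    stop("log-scale ranges need positive bounds", call. = FALSE)
  }
  structure(tibble::tibble(name = name, lower = lower, upper = upper,
                           scale = scale),
            class = c("gq_ranges", class(tibble::tibble())))
}

#' Default exploration ranges
#'
#' The six varied parameters of the global analyses — `k_hyd2`,
#' `effector_bias`, `TRIO_tot`, `PLC_tot`, `RGS_tot`, `k_gef` — each
#' log-uniform over +/- `half_decades` decades around its revised-preset
#' value. This set spans both headline sensitivities (PLC-beta GAP rate,
#' TRIO abundance) and both candidate classifiers (effector bias, GAP
#' rate).
#'
#' The default center is the *initial* preset: the published global batch
#' predates the parameter revision, so the exploration emulates those
#' study conditions (effector bias centered at 1, `k_hyd2` centered at
#' 770-fold over basal hydrolysis).
#'
#' @param params center point, a [gq_params()] object (initial preset by
#'   default).
#' @param half_decades half-width of every range in decades.
#' @return a [param_ranges()] tibble.
#' @export
default_ranges <- function(params = gq_params("initial"),
                           half_decades = 1.5) {
  center <- c(
    k_hyd2 = unname(params$kinetics[["k_hyd2"]]),
    effector_bias = effector_bias(params),
    TRIO_tot = unname(params$totals[["TRIO_tot"]]),
    PLC_tot = unname(params$totals[["PLC_tot"]]),
    RGS_tot = unname(params$totals[["RGS_tot"]]),
    k_gef = unname(params$kinetics[["k_gef"]])
  )
  param_ranges(names(center),
               lower = center * 10^(-half_decades),
               upper = center * 10^(half_decades),
               scale = "log")
}

# Run expr with a local, restorable RNG state seeded by `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.scale_unit <- function(u, ranges) {
  out <- u
  for (j in seq_len(nrow(ranges))) {
    l <- ranges$lower[j]; h <- ranges$upper[j]
    out[, j] <- if (ranges$scale[j] == "log") {
      10^(log10(l) + u[, j] * (log10(h) - log10(l)))
    } else {
      l + u[, j] * (h - l)
    }
  }
  colnames(out) <- ranges$name
  out
}

#' Sample parameter sets
#'
#' Draws parameter sets over the declared ranges. Three schemes:
#'
#' * `"saltelli"` — the cross-sampling design for Sobol sensitivity
#'   analysis. Two independent base matrices A and B of `n_base` rows are
#'   drawn and combined into the blocks A, B, AB_i and BA_i (column i of
#'   one matrix swapped in from the other), giving
#'   `n_base * (2 * D + 2)` rows for D varied parameters. With
#'   `n_base = 800` and `D = 6` this is the 11,200-set design.
#' * `"lhs"` — Latin-hypercube sample of `n_base` rows.
#' * `"random"` — plain uniform sample of `n_base` rows.
#'
#' @param ranges a [param_ranges()] tibble.
#' @param scheme sampling scheme.
#' @param n_base base sample size (per block for Saltelli).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return a tibble of class `gq_batch` with one column per varied symbol
#'   and attributes `scheme`, `n_base`, `seed`, `ranges`, and (Saltelli)
#'   `block` / `base_index` row labels.
#' @export
sample_parameter_sets <- function(ranges, scheme = c("lhs", "saltelli",
                                                     "random"),
                                  n_base = 256, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ranges, "gq_ranges"), n_base >= 1)
  d <- nrow(ranges)
  block <- NULL
  base_index <- NULL
  u <- with_local_seed(seed, {
    if (scheme == "saltelli") {
      if (abs(log2(n_base) - round(log2(n_base))) > 1e-9) {
        warning("Saltelli base sample size is not a power of two; ",
                "index estimates converge more slowly", call. = FALSE)
      }
      A <- matrix(stats::runif(n_base * d), n_base, d)
      B <- matrix(stats::runif(n_base * d), n_base, d)
      blocks <- list(A = A, B = B)
      for (i in seq_len(d)) {
        AB <- A; AB[, i] <- B[, i]
        blocks[[paste0("AB", i)]] <- AB
      }
      for (i in seq_len(d)) {
        BA <- B; BA[, i] <- A[, i]
        blocks[[paste0("BA", i)]] <- BA
      }
      block <- rep(names(blocks), each = n_base)
      base_index <- rep(seq_len(n_base), times = length(blocks))
      do.call(rbind, blocks)
    } else if (scheme == "lhs") {
      # Latin hypercube: stratified permutation per dimension
      vapply(seq_len(d), function(j) {
        (sample(n_base) - stats::runif(n_base)) / n_base
      }, numeric(n_base)) |> matrix(nrow = n_base)
    } else {
      matrix(stats::runif(n_base * d), n_base, d)
    }
  })
  x <- tibble::as_tibble(.scale_unit(u, ranges))
  structure(
    x,
    class = c("gq_batch", class(x)),
    scheme = scheme, n_base = n_base, seed = seed, ranges = ranges,
    block = block, base_index = base_index
  )
}
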