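#' Apply one sampled parameter row to a parameter object
#'
#' Column names must be model symbols (e.g. `k_hyd2`, `TRIO_tot`), the
#' composite `effector_bias` (which moves the Q209L mutant TRIO
#' association scaling `r_at1` with `r_at2` and the dissociation rates
#' held fixed), or inert `dummy*` columns, which are ignored.
#'
#' @param params a [gq_params()] object.
#' @param row one-row data frame or named list/vector of values.
#' @return the modified `gq_params`.
#' @export
apply_row <- function(params, row) {
  row <- as.list(row)
  for (nm in names(row)) {
    if (startsWith(nm, "dummy")) next
    val <- as.numeric(row[[nm]])
    if (nm == "effector_bias") {
      params$variants$Q209L$r_at1 <- val * params$variants$Q209L$r_at2
    } else {
      params <- do.call(set_params,
                        c(list(params), stats::setNames(list(val), nm)))
    }
  }
  validate_params(params)
  params
}

#' Evaluate a batch of parameter sets through the steady-state model
#'
#' For every sampled set, solves the steady state of the all-WT baseline
#' (optional), the heterozygous GNAQ Q209L genotype, and the heterozygous
#' CYSLTR2 L129Q genotype, and records the active-effector readouts and
#' (when the baseline is solved) fold changes. Rows whose solves fail to
#' converge — or that are flagged multistable when `check_multistable` is
#' on — are retained in the table with `converged = FALSE` and excluded
#' from downstream statistics; exclusion counts are stored as attributes.
#'
#' @param batch a `gq_batch` tibble from [sample_parameter_sets()] or
#'   [make_parameter_sets()].
#' @param params fixed parameters for the unsampled symbols (initial
#'   preset by default, matching the published global batch).
#' @param include_wt solve the WT baseline and add fold-change columns.
#' @param check_multistable probe each solve from a second initial
#'   condition (doubles cost; off by default).
#' @return the batch tibble with output columns `trio_q209l`,
#'   `plc_q209l`, `trio_l129q`, `plc_l129q`, optional fold columns, and
#'   `converged`; attributes `n_excluded` and `n_multistable`.
#' @export
evaluate_batch <- function(batch, params = gq_params("initial"),
                           include_wt = TRUE, check_multistable = FALSE) {
  stopifnot(is.data.frame(batch))
  n <- nrow(batch)
  n_multi <- 0L
  solve_quiet <- function(p, g) {
    withCallingHandlers(
      solve_steady_state(p, g, must_converge = FALSE,
                         check_multistable = check_multistable),
      warning = function(w) {
        if (grepl("multistable", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  out <- purrr::map_dfr(seq_len(n), function(i) {
    p <- apply_row(params, batch[i, , drop = FALSE])
    q <- solve_quiet(p, "GNAQ:Q209L:het")
    l <- solve_quiet(p, "CYSLTR2:L129Q:het")
    ok <- q$converged && l$converged && !q$multistable && !l$multistable
    row <- tibble::tibble(
      trio_q209l = q$active_TRIO, plc_q209l = q$active_PLC,
      trio_l129q = l$active_TRIO, plc_l129q = l$active_PLC
    )
    if (include_wt) {
      w <- solve_quiet(p, "WT")
      ok <- ok && w$converged && !w$multistable &&
        w$active_TRIO > 0 && w$active_PLC > 0
      row <- dplyr::mutate(
        row,
        fold_trio_q209l = .data$trio_q209l / w$active_TRIO,
        fold_plc_q209l = .data$plc_q209l / w$active_PLC,
        fold_trio_l129q = .data$trio_l129q / w$active_TRIO,
        fold_plc_l129q = .data$plc_l129q / w$active_PLC
      )
    }
    if (q$multistable || l$multistable) n_multi <<- n_multi + 1L
    dplyr::mutate(row, converged = ok)
  })
  res <- dplyr::bind_cols(tibble::as_tibble(batch), out)
  n_excl <- sum(!out$converged)
  if (n_excl > 0.2 * n) {
    stop(n_excl, "/", n, " parameter sets failed to converge; ",
         "revise the sampling ranges", call. = FALSE)
  }
  for (a in c("scheme", "n_base", "seed", "ranges", "block", "base_index")) {
    attr(res, a) <- attr(batch, a, exact = TRUE)
  }
  attr(res, "n_excluded") <- n_excl
  attr(res, "n_multistable") <- n_multi
  class(res) <- unique(c("gq_batch", class(res)))
  res
}

#' Classify the L129Q-vs-Q209L behavior of each parameter set
#'
#' A pathway readout of the L129Q network is "weak" relative to Q209L when
#' its excess activation over WT is less than `theta` times the Q209L
#' excess: `fold_P(L129Q) - 1 < theta * (fold_P(Q209L) - 1)`. The ERK
#' pathway is proxied by the PLC-beta readout and the YAP pathway by the
#' TRIO readout. Rows whose Q209L fold does not exceed 1 for a pathway are
#' labeled `NA` (undefined) and drop out of the fractions.
#'
#' @param batch an evaluated batch with fold columns
#'   (see [evaluate_batch()] with `include_wt = TRUE`).
#' @param theta weak/strong threshold, default 0.5.
#' @return the batch with a `behavior` column taking values
#'   `"strongERK_weakYAP"`, `"weakERK_strongYAP"`, `"weak_both"`,
#'   `"strong_both"`, or `NA`.
#' @export
classify_behavior <- function(batch, theta = 0.5) {
  need <- c("fold_trio_q209l", "fold_plc_q209l", "fold_trio_l129q",
            "fold_plc_l129q")
  if (!all(need %in% names(batch))) {
    stop("batch lacks fold columns; run evaluate_batch(include_wt = TRUE)",
         call. = FALSE)
  }
  weak <- function(fold_l, fold_q) {
    ifelse(fold_q <= 1, NA, (fold_l - 1) < theta * (fold_q - 1))
  }
  weak_erk <- weak(batch$fold_plc_l129q, batch$fold_plc_q209l)
  weak_yap <- weak(batch$fold_trio_l129q, batch$fold_trio_q209l)
  label <- dplyr::case_when(
    is.na(weak_erk) | is.na(weak_yap) ~ NA_character_,
    !weak_erk & weak_yap ~ "strongERK_weakYAP",
    weak_erk & !weak_yap ~ "weakERK_strongYAP",
    weak_erk & weak_yap ~ "weak_both",
    TRUE ~ "strong_both"
  )
  if ("converged" %in% names(batch)) label[!batch$converged] <- NA
  dplyr::mutate(batch, behavior = label)
}

#' Behavior-class fractions with threshold sensitivity
#'
#' @param batch an evaluated batch.
#' @param theta vector of weak/strong thresholds to report.
#' @return tibble: `theta`, `behavior`, `n`, `fraction` (over rows with a
#'   defined label at that theta).
#' @export
behavior_fractions <- function(batch, theta = c(0.25, 0.5, 0.75)) {
  purrr::map_dfr(theta, function(th) {
    lab <- classify_behavior(batch, theta = th)$behavior
    lab <- lab[!is.na(lab)]
    all_levels <- c("strongERK_weakYAP", "weakERK_strongYAP",
                    "weak_both", "strong_both")
    counts <- table(factor(lab, levels = all_levels))
    tibble::tibble(theta = th, behavior = all_levels,
                   n = as.integer(counts),
                   fraction = as.numeric(counts) / max(length(lab), 1))
  })
}

#' Experiment-match flag
#'
#' The published predicate: a parameter set matches the experimental
#' activation pattern iff the L129Q network yields greater than or equal
#' PLC-beta activation AND strictly lower TRIO activation than the Q209L
#' network.
#'
#' @param batch an evaluated batch (readout columns required).
#' @return the batch with a logical `match` column (`NA` for excluded
#'   rows).
#' @export
match_experiment <- function(batch) {
  need <- c("trio_q209l", "plc_q209l", "trio_l129q", "plc_l129q")
  if (!all(need %in% names(batch))) {
    stop("batch lacks readout columns; run evaluate_batch() first",
         call. = FALSE)
  }
  m <- batch$plc_l129q >= batch$plc_q209l & batch$trio_l129q < batch$trio_q209l
  if ("converged" %in% names(batch)) m[!batch$converged] <- NA
  dplyr::mutate(batch, match = m)
}
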