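#' Co-mutation enrichment inputs
#'
#' The four summary counts behind the exact co-occurrence probability:
#' `N` patients in the cohort, `x` carriers of the index-gene mutation,
#' `y` carriers of any pathway-family mutation, and `k` patients carrying
#' both.
#'
#' @param N,x,y,k nonnegative integer counts.
#' @return a validated list of class `gq_enrichment_inputs`.
#' @examples
#' enrichment_inputs(80, 3, 4, 2)   # the TCGA uveal melanoma counts
#' @export
enrichment_inputs <- function(N, x, y, k) {
  vals <- c(N = N, x = x, y = y, k = k)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("N, x, y, k must be nonnegative integers", call. = FALSE)
  }
  if (x > N) stop("invariant violated: x <= N", call. = FALSE)
  if (y > N) stop("invariant violated: y <= N", call. = FALSE)
  if (k > min(x, y)) stop("invariant violated: k <= min(x, y)", call. = FALSE)
  if (x + y - k > N) stop("invariant violated: x + y - k <= N", call. = FALSE)
  structure(as.list(vals), class = "gq_enrichment_inputs")
}

#' Exact co-mutation enrichment probability (point mass)
#'
#' The probability that an x-patient index-mutant set and a y-patient
#' family-mutant set, each placed uniformly at random among N patients,
#' overlap in exactly k patients:
#' \deqn{\frac{(N-k)!}{(x-k)!\,(y-k)!\,(N+k-x-y)!}\;
#'       \frac{\binom{N}{k}}{\binom{N}{x}\binom{N}{y}}}
#' evaluated in log-factorial space, numerically stable for N up to 1e5.
#' This is identical to the hypergeometric point mass
#' `choose(x,k) choose(N-x, y-k) / choose(N,y)`; the identity is verified
#' exhaustively in the test suite and on demand via [enrichment_test()].
#'
#' @param inputs an [enrichment_inputs()] object (or N, given the
#'   remaining counts).
#' @param x,y,k counts, when `inputs` is given as the scalar N.
#' @return the point probability, a number in `[0, 1]`.
#' @examples
#' enrichment_probability(enrichment_inputs(80, 3, 4, 2))
#' @export
enrichment_probability <- function(inputs, x = NULL, y = NULL, k = NULL) {
  if (!inherits(inputs, "gq_enrichment_inputs")) {
    inputs <- enrichment_inputs(inputs, x, y, k)
  }
  N <- inputs$N; x <- inputs$x; y <- inputs$y; k <- inputs$k
  lchoose_ <- function(n, r) lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
  lp <- lgamma(N - k + 1) - lgamma(x - k + 1) - lgamma(y - k + 1) -
    lgamma(N + k - x - y + 1) +
    lchoose_(N, k) - lchoose_(N, x) - lchoose_(N, y)
  min(exp(lp), 1)
}

#' Monte-Carlo estimate of the enrichment probability
#'
#' Draws the x-set and y-set uniformly and independently from N patients
#' and counts how often the overlap is exactly k. Returned with the
#' binomial standard error; seed-deterministic.
#'
#' @param inputs an [enrichment_inputs()] object.
#' @param n_draws number of random placements (at least 1e4).
#' @param seed integer seed.
#' @return tibble: `p_mc`, `se`, `n_draws`, `seed`.
#' @export
mc_enrichment <- function(inputs, n_draws = 1e5, seed = 1) {
  stopifnot(inherits(inputs, "gq_enrichment_inputs"))
  if (n_draws < 1e4) stop("n_draws must be at least 1e4", call. = FALSE)
  N <- inputs$N; x <- inputs$x; y <- inputs$y; k <- inputs$k
  hits <- with_local_seed(seed, {
    sum(vapply(seq_len(n_draws), function(i) {
      xs <- sample.int(N, x)
      ys <- sample.int(N, y)
      sum(xs %in% ys) == k
    }, logical(1)))
  })
  p <- hits / n_draws
  tibble::tibble(p_mc = p, se = sqrt(p * (1 - p) / n_draws),
                 n_draws = n_draws, seed = seed)
}

#' Full enrichment report
#'
#' Computes the exact point probability, the independent hypergeometric
#' point-mass evaluation (`stats::dhyper`), the right-tail probability
#' `P(K >= k)` (the conventional "at least this much overlap" enrichment
#' question; the point mass is the primary quantity), and optionally a
#' Monte-Carlo estimate.
#'
#' @param inputs an [enrichment_inputs()] object.
#' @param mc_draws Monte-Carlo draws; `0` skips the Monte-Carlo check.
#' @param seed seed for the Monte-Carlo draws.
#' @return one-row tibble of class `gq_enrichment`: `N`, `x`, `y`, `k`,
#'   `p_point`, `p_hypergeom`, `p_tail`, and when requested `p_mc`,
#'   `mc_se`, `mc_draws`.
#' @examples
#' enrichment_test(enrichment_inputs(80, 3, 4, 2), mc_draws = 0)
#' @export
enrichment_test <- function(inputs, mc_draws = 0, seed = 1) {
  stopifnot(inherits(inputs, "gq_enrichment_inputs"))
  N <- inputs$N; x <- inputs$x; y <- inputs$y; k <- inputs$k
  p_point <- enrichment_probability(inputs)
  p_hyper <- stats::dhyper(k, x, N - x, y)
  kmax <- min(x, y)
  p_tail <- sum(stats::dhyper(k:kmax, x, N - x, y))
  out <- tibble::tibble(N = N, x = x, y = y, k = k,
                        p_point = p_point, p_hypergeom = p_hyper,
                        p_tail = min(p_tail, 1))
  if (mc_draws > 0) {
    mc <- mc_enrichment(inputs, n_draws = mc_draws, seed = seed)
    out <- dplyr::mutate(out, p_mc = mc$p_mc, mc_se = mc$se,
                         mc_draws = mc$n_draws)
  }
  structure(out, class = c("gq_enrichment", class(out)))
}

#' Summarize a cohort mutation table into enrichment inputs
#'
#' @param table a long-form mutation table with columns `patient_id` and
#'   `gene` (MAF-like; extra columns such as `variant` are ignored), or a
#'   wide logical patient-by-gene data frame with a `patient_id` column.
#' @param index_gene the index gene (e.g. `"CYSLTR2"`).
#' @param family_genes character vector of pathway-family genes (e.g. the
#'   semaphorin/plexin list shipped at
#'   `system.file("extdata", "sema_plexin_genes.txt", package = "gqcycle")`).
#' @return an [enrichment_inputs()] object with `N` = number of patients,
#'   `x` = index-gene carriers, `y` = patients with at least one
#'   family-gene mutation, `k` = the overlap.
#' @export
table_to_inputs <- function(table, index_gene, family_genes) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("empty cohort table", call. = FALSE)
  if (!"patient_id" %in% names(table)) {
    stop("cohort table needs a patient_id column", call. = FALSE)
  }
  if ("gene" %in% names(table)) {
    patients <- unique(table$patient_id)
    idx <- unique(table$patient_id[table$gene == index_gene])
    fam <- unique(table$patient_id[table$gene %in% family_genes])
  } else {
    # wide logical layout
    patients <- table$patient_id
    genes <- setdiff(names(table), "patient_id")
    if (!index_gene %in% genes) {
      stop("index gene ", index_gene, " not in table columns", call. = FALSE)
    }
    idx <- patients[as.logical(table[[index_gene]])]
    fam_cols <- intersect(family_genes, genes)
    fam <- patients[rowSums(as.matrix(table[fam_cols])) > 0]
  }
  enrichment_inputs(length(patients), length(idx), length(fam),
                    length(intersect(idx, fam)))
}

#' Read the shipped semaphorin/plexin gene list
#'
#' A curated 29-gene stand-in for the semaphorin/plexin ligand/receptor
#' family (20 semaphorins, 9 plexins); the exact family membership used in
#' the published cohort analysis is not enumerated in the source text, so
#' this list is user-replaceable.
#'
#' @param path optional path to a user gene list (one symbol per line,
#'   `#` comments allowed).
#' @return character vector of gene symbols.
#' @export
sema_plexin_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sema_plexin_genes.txt",
                        package = "gqcycle")
  }
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
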