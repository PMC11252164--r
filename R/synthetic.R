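#' Synthetic patient cohort with planted co-mutation structure
#'
#' Generates a long-form mutation table (`patient_id`, `gene`, `variant`)
#' with known ground truth: exactly `x` carriers of the index gene,
#' exactly `y` carriers of at least one pathway-family gene, and exactly
#' `k` patients carrying both. All other genes are background genes
#' mutated i.i.d. at `background_rate`, after which per-patient coding
#' mutation counts are nudged into `burden_band` to emulate the low
#' mutation burden of uveal melanoma exomes (5–19 coding mutations per
#' sample). Seed-deterministic; the generating spec is attached as a
#' `manifest` attribute.
#'
#' @param N,x,y,k planted summary counts (must form a valid
#'   [enrichment_inputs()] quadruple).
#' @param background_rate per-patient per-gene background mutation
#'   probability.
#' @param seed integer seed.
#' @param index_gene index gene symbol.
#' @param family_genes pathway-family gene symbols
#'   ([sema_plexin_genes()] by default).
#' @param n_genes total gene universe (index + family + background).
#' @param burden_band inclusive per-patient total mutation count band.
#' @return tibble of class `gq_cohort` in long form; patients with no
#'   mutations still appear (with `gene = NA`) so `N` is recoverable.
#' @examples
#' coh <- make_cohort(80, 3, 4, 2, seed = 7)
#' table_to_inputs(coh, "CYSLTR2", sema_plexin_genes())
#' @export
make_cohort <- function(N, x, y, k, background_rate = 0.05, seed = 1,
                        index_gene = "CYSLTR2",
                        family_genes = sema_plexin_genes(),
                        n_genes = 200, burden_band = c(5, 19)) {
  inputs <- enrichment_inputs(N, x, y, k)  # validates feasibility
  n_bg <- n_genes - 1 - length(family_genes)
  if (n_bg < burden_band[2]) {
    stop("gene universe too small for the requested burden band",
         call. = FALSE)
  }
  bg_genes <- sprintf("BG%03d", seq_len(n_bg))

  tab <- with_local_seed(seed, {
    idx_carriers <- sample.int(N, x)
    fam_overlap <- sample(idx_carriers, k)
    fam_only <- sample(setdiff(seq_len(N), idx_carriers), y - k)
    fam_carriers <- c(fam_overlap, fam_only)

    purrr::map_dfr(seq_len(N), function(i) {
      genes <- character(0)
      if (i %in% idx_carriers) genes <- c(genes, index_gene)
      if (i %in% fam_carriers) genes <- c(genes, sample(family_genes, 1))
      bg <- bg_genes[stats::runif(n_bg) < background_rate]
      need <- burden_band[1] - length(genes) - length(bg)
      if (need > 0) {
        bg <- union(bg, sample(setdiff(bg_genes, bg), need))
      }
      excess <- length(genes) + length(bg) - burden_band[2]
      if (excess > 0) bg <- bg[seq_len(length(bg) - excess)]
      genes <- c(genes, bg)
      if (length(genes) == 0) {
        tibble::tibble(patient_id = sprintf("P%03d", i), gene = NA_character_,
                       variant = NA_character_)
      } else {
        tibble::tibble(patient_id = sprintf("P%03d", i), gene = genes,
                       variant = "mut")
      }
    })
  })
  structure(
    tab,
    class = c("gq_cohort", class(tab)),
    manifest = list(
      generator = "make_cohort",
      spec = list(N = N, x = x, y = y, k = k,
                  background_rate = background_rate,
                  index_gene = index_gene, n_genes = n_genes,
                  burden_band = burden_band),
      seed = seed,
      package_version = as.character(utils::packageVersion("gqcycle"))
    )
  )
}

#' Sampled parameter sets with a manifest
#'
#' Thin synthetic-data wrapper over [sample_parameter_sets()]; exists so
#' tests and pipelines can generate reproducible input batches without a
#' model run, and so every generated batch carries a manifest.
#'
#' @inheritParams sample_parameter_sets
#' @param n base sample size (alias of `n_base`).
#' @return a `gq_batch` tibble with a `manifest` attribute.
#' @export
make_parameter_sets <- function(ranges = default_ranges(), n = 256,
                                seed = 1, scheme = "lhs") {
  batch <- sample_parameter_sets(ranges, scheme = scheme, n_base = n,
                                 seed = seed)
  attr(batch, "manifest") <- list(
    generator = "make_parameter_sets",
    spec = list(ranges = as.data.frame(ranges), n = n, scheme = scheme),
    seed = seed,
    package_version = as.character(utils::packageVersion("gqcycle"))
  )
  batch
}

#' Reduced single-pool cycle with an analytic steady state
#'
#' A toy fixture used as an independent oracle for the full solver: one
#' G-alpha pool, no RGS, no PLC-beta (hence no PLC GAP), no
#' nucleotide-free branch. At steady state the balance equations reduce
#' to a single monotone scalar equation in free GaGTP:
#' exchange flux = hydrolysis flux, effector binding at detailed balance,
#' GaGDP set by the reassociation balance, closed by G-alpha
#' conservation. The fixture solves this reduction with a bracketed root
#' find at 1e-14 tolerance, independently of the ODE path.
#'
#' @param k_gef,k_hyd,k_at1,k_dt1,k_trimer positive rate constants.
#' @param f_act receptor active fraction.
#' @param Ga_tot,Gbg_tot,TRIO_tot,R_tot abundances (`Gbg_tot >= Ga_tot`).
#' @return a list of class `gq_toy_fixture` with elements `params` (a
#'   [gq_params()] object realizing the reduction inside the full model),
#'   `closed_form` (named steady-state vector in the full species layout),
#'   and the scalar balance residual at the returned root.
#' @export
make_toy_fixture <- function(k_gef = 10, k_hyd = 0.013, k_at1 = 10,
                             k_dt1 = 1, k_trimer = 100, f_act = 0.01,
                             Ga_tot = 1, Gbg_tot = 1, TRIO_tot = 0.5,
                             R_tot = 1) {
  stopifnot(Gbg_tot >= Ga_tot)
  params <- gq_params(
    "revised",
    k_gef = k_gef, k_hyd = k_hyd, k_at1 = k_at1, k_dt1 = k_dt1,
    k_trimer = k_trimer, f_act_wt = f_act,
    Ga_tot = Ga_tot, Gbg_tot = Gbg_tot, TRIO_tot = TRIO_tot, R_tot = R_tot,
    RGS_tot = 0, PLC_tot = 0, k_gtp_off = 0
  )
  a <- k_gef * f_act * R_tot
  species <- gq_species_names()
  state <- stats::setNames(numeric(length(species)), species)
  state[["Gbg"]] <- Gbg_tot - Ga_tot
  state[["TRIO"]] <- TRIO_tot

  if (a == 0) {
    state[["HT_wt"]] <- Ga_tot
    g <- 0
    resid <- 0
  } else {
    K1 <- k_at1 / k_dt1
    pieces <- function(g) {
      HT <- k_hyd * g / a
      Gbg_free <- Gbg_tot - HT
      GDP <- k_hyd * g / (k_trimer * Gbg_free)
      GT <- K1 * g * TRIO_tot / (1 + K1 * g)
      list(HT = HT, GDP = GDP, GT = GT, Gbg_free = Gbg_free)
    }
    balance <- function(g) {
      p <- pieces(g)
      p$HT + g + p$GDP + p$GT - Ga_tot
    }
    g <- stats::uniroot(balance, c(0, Ga_tot), tol = 1e-15)$root
    # polish by bisection-free Newton steps on the smooth scalar equation
    for (i in 1:5) {
      h <- max(g * 1e-8, 1e-14)
      slope <- (balance(g + h) - balance(g - h)) / (2 * h)
      g <- g - balance(g) / slope
    }
    p <- pieces(g)
    state[["HT_wt"]] <- p$HT
    state[["GTP_wt"]] <- g
    state[["GDP_wt"]] <- p$GDP
    state[["GT_TRIO_wt"]] <- p$GT
    state[["TRIO"]] <- TRIO_tot - p$GT
    state[["Gbg"]] <- p$Gbg_free
    resid <- balance(g)
  }
  structure(
    list(params = params, closed_form = state, free_GaGTP = g,
         balance_residual = resid),
    class = "gq_toy_fixture"
  )
}
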