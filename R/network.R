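#' @useDynLib gqcycle
#' @importFrom rlang .data
NULL

# Species layout shared between the R reference RHS and the compiled RHS.
gq_species_names <- function() {
  per_pool <- c("HT", "GDP", "GTP", "EMPTY", "GT_TRIO", "GT_PLC",
                "RGS_GA", "GDP_D", "HT_D")
  c(paste0(per_pool, "_wt"), paste0(per_pool, "_mut"),
    "Gbg", "TRIO", "PLC", "RGS")
}

#' Build the reaction network for a genotype
#'
#' Assembles everything the solver needs: the species list, the numeric
#' parameter vector consumed by the mass-action right-hand side, the
#' initial condition (all G-alpha in heterotrimer, all effectors, RGS and
#' Gbg free), and the conservation groups. WT and mutant G-alpha species
#' are distinct state variables throughout; both active-receptor pools act
#' identically on both G-alpha pools (the receptor is catalytic and enters
#' only through the effective active-receptor concentration).
#'
#' @param params a [gq_params()] object.
#' @param genotype a [gq_genotype()] or genotype string.
#' @param drug optional [gq_drug()] object; `NULL` for the drug-free model.
#' @param dose clamped drug concentration (ignored when `drug` is `NULL`).
#' @param stimulated if `TRUE`, the WT receptor active fraction is replaced
#'   by `params$stimulated_f_act` (ligand-stimulated conditions).
#' @return a list of class `gq_network` with elements `species`, `parms`
#'   (length-27 numeric for the compiled RHS), `y0`, `conservation`
#'   (named list of index vectors and their conserved totals), `params`,
#'   `genotype`, `allocation`.
#' @export
build_network <- function(params, genotype = "WT", drug = NULL, dose = 0,
                          stimulated = FALSE) {
  validate_params(params)
  g <- parse_genotype(genotype)
  alloc <- allocate_genotype(g, params)
  kin <- params$kinetics
  tot <- params$totals

  f_wt <- if (stimulated) params$stimulated_f_act else params$f_act_wt
  # Effective catalytic GEF activity: both receptor pools act on both
  # G-alpha pools, so only the total active-receptor concentration matters.
  Ract <- tot[["R_tot"]] *
    ((1 - alloc$receptor_mut_frac) * f_wt +
       alloc$receptor_mut_frac * alloc$scalings$f_act_mut)

  sc <- alloc$scalings
  drug_parms <- c(k_on_drug = 0, k_off_drug = 0, dose = 0,
                  bind_free = 0, bind_ht = 0)
  if (!is.null(drug)) {
    stopifnot(inherits(drug, "gq_drug"))
    if (dose < 0) stop("drug dose must be nonnegative", call. = FALSE)
    drug_parms <- c(k_on_drug = drug$k_on, k_off_drug = drug$k_off,
                    dose = dose,
                    bind_free = as.numeric("free_GaGDP" %in% drug$targets),
                    bind_ht = as.numeric("heterotrimer" %in% drug$targets))
  }

  parms <- c(
    kin[c("k_gef", "k_hyd", "k_rgs_on", "k_rgs_off", "k_rgs_cat",
          "k_at1", "k_dt1", "k_at2", "k_dt2", "k_hyd2",
          "k_gtp_off", "k_nt_load", "k_trimer")],
    Ract = unname(Ract),
    s_hyd_wt = 1, s_hyd_mut = sc$r_hyd,
    s_gap_wt = 1, s_gap_mut = sc$r_gap,
    s_at1_wt = 1, s_at1_mut = sc$r_at1,
    s_at2_wt = 1, s_at2_mut = sc$r_at2,
    drug_parms
  )

  species <- gq_species_names()
  y0 <- stats::setNames(numeric(length(species)), species)
  ga_wt <- tot[["Ga_tot"]] * (1 - alloc$galpha_mut_frac)
  ga_mut <- tot[["Ga_tot"]] * alloc$galpha_mut_frac
  if (tot[["Gbg_tot"]] < tot[["Ga_tot"]]) {
    stop("Gbg_tot must be at least Ga_tot so every heterotrimer can form",
         call. = FALSE)
  }
  y0[["HT_wt"]] <- ga_wt
  y0[["HT_mut"]] <- ga_mut
  y0[["Gbg"]] <- tot[["Gbg_tot"]] - tot[["Ga_tot"]]
  y0[["TRIO"]] <- tot[["TRIO_tot"]]
  y0[["PLC"]] <- tot[["PLC_tot"]]
  y0[["RGS"]] <- tot[["RGS_tot"]]

  ga_members <- function(suffix) {
    paste0(c("HT", "GDP", "GTP", "EMPTY", "GT_TRIO", "GT_PLC",
             "RGS_GA", "GDP_D", "HT_D"), suffix)
  }
  conservation <- list(
    Ga_wt = list(idx = match(ga_members("_wt"), species), total = ga_wt),
    Ga_mut = list(idx = match(ga_members("_mut"), species), total = ga_mut),
    Gbg = list(idx = match(c("Gbg", "HT_wt", "HT_mut", "HT_D_wt", "HT_D_mut"),
                           species), total = tot[["Gbg_tot"]]),
    TRIO = list(idx = match(c("TRIO", "GT_TRIO_wt", "GT_TRIO_mut"), species),
                total = tot[["TRIO_tot"]]),
    PLC = list(idx = match(c("PLC", "GT_PLC_wt", "GT_PLC_mut"), species),
               total = tot[["PLC_tot"]]),
    RGS = list(idx = match(c("RGS", "RGS_GA_wt", "RGS_GA_mut"), species),
               total = tot[["RGS_tot"]])
  )

  structure(
    list(species = species, parms = parms, y0 = y0,
         conservation = conservation, params = params, genotype = g,
         allocation = alloc),
    class = "gq_network"
  )
}

#' Mass-action time derivative (reference implementation)
#'
#' Pure-R evaluation of the reaction list, written reaction by reaction so
#' each flux can be audited independently of the compiled solver path. The
#' compiled RHS used by [solve_steady_state()] must agree with this
#' function to machine precision; tests enforce that.
#'
#' @param state named numeric state vector in the [build_network()] layout.
#' @param network a `gq_network` object.
#' @return named numeric derivative vector.
#' @export
gq_rhs <- function(state, network) {
  if (length(state) != length(network$species)) {
    stop("state has ", length(state), " entries; network expects ",
         length(network$species), call. = FALSE)
  }
  y <- stats::setNames(as.numeric(state), network$species)
  p <- network$parms
  d <- stats::setNames(numeric(length(y)), names(y))

  for (pool in c("wt", "mut")) {
    s <- function(nm) y[[paste0(nm, "_", pool)]]
    add <- function(nm, v) {
      key <- if (nm %in% c("Gbg", "TRIO", "PLC", "RGS")) nm
             else paste0(nm, "_", pool)
      d[[key]] <<- d[[key]] + v
    }
    s_hyd <- p[[paste0("s_hyd_", pool)]]
    s_gap <- p[[paste0("s_gap_", pool)]]
    s_at1 <- p[[paste0("s_at1_", pool)]]
    s_at2 <- p[[paste0("s_at2_", pool)]]

    # (1) receptor-catalyzed exchange: HT -> GaGTP + Gbg
    v <- p[["k_gef"]] * p[["Ract"]] * s("HT")
    add("HT", -v); add("GTP", v); add("Gbg", v)
    # (2) intrinsic hydrolysis: GaGTP -> GaGDP
    v <- p[["k_hyd"]] * s_hyd * s("GTP")
    add("GTP", -v); add("GDP", v)
    # (3) RGS GAP cycle
    v <- p[["k_rgs_on"]] * y[["RGS"]] * s("GTP")
    add("RGS", -v); add("GTP", -v); add("RGS_GA", v)
    v <- p[["k_rgs_off"]] * s("RGS_GA")
    add("RGS_GA", -v); add("RGS", v); add("GTP", v)
    v <- p[["k_rgs_cat"]] * s_gap * s("RGS_GA")
    add("RGS_GA", -v); add("RGS", v); add("GDP", v)
    # (4) TRIO effector binding
    v <- p[["k_at1"]] * s_at1 * s("GTP") * y[["TRIO"]]
    add("GTP", -v); add("TRIO", -v); add("GT_TRIO", v)
    v <- p[["k_dt1"]] * s("GT_TRIO")
    add("GT_TRIO", -v); add("GTP", v); add("TRIO", v)
    # (5) PLC effector binding
    v <- p[["k_at2"]] * s_at2 * s("GTP") * y[["PLC"]]
    add("GTP", -v); add("PLC", -v); add("GT_PLC", v)
    v <- p[["k_dt2"]] * s("GT_PLC")
    add("GT_PLC", -v); add("GTP", v); add("PLC", v)
    # (6) PLC acting as GAP on its own complex
    v <- p[["k_hyd2"]] * s_gap * s("GT_PLC")
    add("GT_PLC", -v); add("GDP", v); add("PLC", v)
    # (7) nucleotide release / reloading
    v <- p[["k_gtp_off"]] * s("GTP")
    add("GTP", -v); add("EMPTY", v)
    v <- p[["k_nt_load"]] * s("EMPTY")
    add("EMPTY", -v); add("GTP", v)
    # (8) heterotrimer reassociation
    v <- p[["k_trimer"]] * s("GDP") * y[["Gbg"]]
    add("GDP", -v); add("Gbg", -v); add("HT", v)
    # GDI drug binding (clamped dose)
    v <- p[["k_on_drug"]] * p[["dose"]] * s("GDP") * p[["bind_free"]]
    add("GDP", -v); add("GDP_D", v)
    v <- p[["k_off_drug"]] * s("GDP_D")
    add("GDP_D", -v); add("GDP", v)
    v <- p[["k_on_drug"]] * p[["dose"]] * s("HT") * p[["bind_ht"]]
    add("HT", -v); add("HT_D", v)
    v <- p[["k_off_drug"]] * s("HT_D")
    add("HT_D", -v); add("HT", v)
  }
  d
}

# Evaluate the compiled RHS once, by taking a single explicit-Euler step of
# size h and differencing: f(y) = (euler_step(y, h) - y) / h exactly.
# Used only in tests to confirm the C and R implementations agree.
gq_rhs_compiled <- function(state, network, h = 1) {
  y0 <- as.numeric(state)
  out <- deSolve::ode(
    y = y0, times = c(0, h), func = "gq_derivs", parms = network$parms,
    dllname = "gqcycle", initfunc = "gq_initmod", method = "euler"
  )
  stats::setNames((out[2, -1] - y0) / h, network$species)
}

#' Check conservation of every protein total
#'
#' @param state named state vector.
#' @param network a `gq_network`.
#' @return tibble with one row per conservation group: the group name, its
#'   expected total, the realized sum, and the relative error.
#' @export
conservation_check <- function(state, network) {
  y <- as.numeric(state)
  scale <- max(network$params$totals)
  purrr::imap_dfr(network$conservation, function(grp, nm) {
    s <- sum(y[grp$idx])
    tibble::tibble(
      group = nm, total = grp$total, realized = s,
      rel_error = abs(s - grp$total) / scale
    )
  })
}
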