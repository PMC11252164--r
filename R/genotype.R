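#' Genotype specification
#'
#' A genotype names one mutated gene, the variant, and its zygosity.
#' The model treats GNAQ and GNA11 as biochemically identical G-alpha
#' genes, each holding half of the total G-alpha pool, so a heterozygous
#' G-alpha variant mutates one of the four alleles (25% of the pool) and a
#' homozygous variant mutates both alleles of one gene (50% of the pool).
#' CYSLTR2 variants act at the receptor level instead.
#'
#' @param gene one of `"GNAQ"`, `"GNA11"`, `"CYSLTR2"`. Ignored (with the
#'   variant forced to WT) when `variant = "WT"`.
#' @param variant one of `"WT"`, `"Q209L"`, `"Q209P"`, `"R183C"` (G-alpha
#'   genes only) or `"L129Q"` (CYSLTR2 only).
#' @param zygosity `"het"` or `"hom"`; ignored for WT.
#' @return An object of class `gq_genotype` with fields `gene`, `variant`,
#'   `zygosity`.
#' @examples
#' gq_genotype("GNAQ", "Q209L", "het")
#' parse_genotype("CYSLTR2:L129Q:het")
#' @export
gq_genotype <- function(gene = "GNAQ", variant = "WT", zygosity = "het") {
  gene <- match.arg(toupper(gene), c("GNAQ", "GNA11", "CYSLTR2"))
  variant <- match.arg(variant, c("WT", "Q209L", "Q209P", "R183C", "L129Q"))
  zygosity <- match.arg(zygosity, c("het", "hom"))
  galpha_variants <- c("Q209L", "Q209P", "R183C")
  if (variant %in% galpha_variants && !gene %in% c("GNAQ", "GNA11")) {
    stop(variant, " is a G-alpha variant; gene must be GNAQ or GNA11",
         call. = FALSE)
  }
  if (variant == "L129Q" && gene != "CYSLTR2") {
    stop("L129Q is a receptor variant; gene must be CYSLTR2", call. = FALSE)
  }
  structure(list(gene = gene, variant = variant, zygosity = zygosity),
            class = "gq_genotype")
}

#' Parse a `GENE:VARIANT:ZYGOSITY` genotype string
#'
#' @param x a string such as `"GNAQ:Q209L:het"`; `"WT"` and `"GNAQ:WT"`
#'   are accepted shorthands for the all-wild-type genotype.
#' @return a [gq_genotype()] object.
#' @export
parse_genotype <- function(x) {
  if (inherits(x, "gq_genotype")) return(x)
  stopifnot(is.character(x), length(x) == 1)
  parts <- strsplit(trimws(x), ":", fixed = TRUE)[[1]]
  if (length(parts) == 1 && toupper(parts) == "WT") {
    return(gq_genotype("GNAQ", "WT"))
  }
  if (length(parts) == 2) parts <- c(parts, "het")
  if (length(parts) != 3) {
    stop("genotype string must be GENE:VARIANT:ZYGOSITY, got: ", x,
         call. = FALSE)
  }
  gq_genotype(parts[1], parts[2], parts[3])
}

#' @export
print.gq_genotype <- function(x, ...) {
  if (x$variant == "WT") cat("<gq_genotype> WT/WT\n")
  else cat("<gq_genotype>", paste(x$gene, x$variant, x$zygosity, sep = ":"),
           "\n")
  invisible(x)
}

#' @export
format.gq_genotype <- function(x, ...) {
  if (x$variant == "WT") "WT" else paste(x$gene, x$variant, x$zygosity,
                                         sep = ":")
}

#' Translate a genotype into species-pool allocations
#'
#' Heterozygous G-alpha variants allocate 25% of the total G-alpha pool to
#' the mutant species (one of four biochemically identical GNAQ/GNA11
#' alleles); homozygous variants allocate 50% (the mutated gene's whole
#' share). The receptor variant CYSLTR2 L129Q allocates 50% mutant
#' receptor when heterozygous; the homozygous receptor case (100%) is not
#' described by the underlying study and is flagged experimental via a
#' warning. Total protein abundances are never changed by genotype.
#'
#' @param genotype a [gq_genotype()] object or genotype string.
#' @param params a [gq_params()] object supplying the variant scaling
#'   bundles.
#' @return a list with `galpha_mut_frac`, `receptor_mut_frac`, and
#'   `scalings` (the `r_at1`, `r_at2`, `r_hyd`, `r_gap`, `f_act_mut`
#'   bundle applied to mutant species).
#' @examples
#' allocate_genotype("GNAQ:Q209L:het")$galpha_mut_frac   # 0.25
#' allocate_genotype("CYSLTR2:L129Q:het")$receptor_mut_frac  # 0.5
#' @export
allocate_genotype <- function(genotype, params = gq_params()) {
  g <- parse_genotype(genotype)
  scalings <- list(r_at1 = 1, r_at2 = 1, r_hyd = 1, r_gap = 1, f_act_mut = 0)
  if (g$variant == "WT") {
    return(list(galpha_mut_frac = 0, receptor_mut_frac = 0,
                scalings = scalings))
  }
  bundle <- params$variants[[g$variant]]
  if (is.null(bundle)) {
    stop("no scaling bundle for variant ", g$variant,
         " in the supplied parameters", call. = FALSE)
  }
  scalings <- utils::modifyList(scalings, bundle)
  if (g$gene %in% c("GNAQ", "GNA11")) {
    list(
      galpha_mut_frac = if (g$zygosity == "het") 0.25 else 0.5,
      receptor_mut_frac = 0,
      scalings = scalings
    )
  } else {
    if (g$zygosity == "hom") {
      warning("homozygous CYSLTR2 L129Q (100% mutant receptor) is an ",
              "experimental extrapolation", call. = FALSE)
    }
    list(
      galpha_mut_frac = 0,
      receptor_mut_frac = if (g$zygosity == "het") 0.5 else 1,
      scalings = scalings
    )
  }
}
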