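#' Load and validate a model configuration file
#'
#' Reads a YAML (or JSON) configuration holding a flat map of parameter
#' symbol to value, an optional `preset` name, an optional `genotype`
#' block (either a `GENE:VARIANT:ZYGOSITY` string or a map with those
#' three keys), and optional per-variant scaling overrides under
#' `variants`. Unknown keys are rejected with the offending key named;
#' missing keys are filled from the named preset. The fully resolved
#' configuration is what [run_manifest()] echoes.
#'
#' @param path path to the config file; an empty or missing-key file plus
#'   `preset` yields the full preset.
#' @param preset preset used for unspecified symbols, overridden by a
#'   `preset` key in the file.
#' @return a list with `params` (a [gq_params()]), `genotype` (a
#'   [gq_genotype()]), and `options` (any `stage_options` block, as-is).
#' @export
load_config <- function(path, preset = "revised") {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)

  if (!is.null(raw$preset)) preset <- raw$preset
  params <- gq_params(preset)
  genotype <- gq_genotype("GNAQ", "WT")
  options <- list()

  known_scalars <- c(names(params$kinetics), names(params$totals),
                     "f_act_wt", "stimulated_f_act")
  for (key in names(raw)) {
    val <- raw[[key]]
    if (key == "preset") next
    if (key == "genotype") {
      genotype <- if (is.character(val)) parse_genotype(val)
                  else gq_genotype(val$gene, val$variant,
                                   val$zygosity %||% "het")
    } else if (key == "variants") {
      params <- set_params(params, variants = val)
    } else if (key == "stage_options") {
      options <- val
    } else if (key %in% known_scalars) {
      params <- do.call(set_params,
                        c(list(params), stats::setNames(list(val), key)))
    } else {
      stop("unknown config key: ", key, call. = FALSE)
    }
  }
  list(params = params, genotype = genotype, options = options)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a run manifest
#'
#' Every pipeline run emits a manifest: the subcommand, the fully
#' resolved configuration (all defaults materialized as a flat symbol
#' map), seeds, package version, digests of input/output files, and
#' wall-clock bounds. Re-running from the manifest reproduces
#' deterministic stages bit-for-bit.
#'
#' @param subcommand stage name.
#' @param params resolved [gq_params()].
#' @param genotype resolved genotype (or `NULL`).
#' @param seed seed in effect (or `NULL`).
#' @param files named character vector of input/output paths to digest.
#' @param extra further metadata to embed.
#' @param started POSIXct start time.
#' @return a list ready for [write_manifest()].
#' @export
run_manifest <- function(subcommand, params, genotype = NULL, seed = NULL,
                         files = character(0), extra = list(),
                         started = Sys.time()) {
  digest_file <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    # cheap content digest: size + sum of bytes (no external digest dep)
    bytes <- readBin(f, "raw", n = file.info(f)$size)
    sprintf("size:%d;sum:%.0f", length(bytes), sum(as.integer(bytes)))
  }
  list(
    subcommand = subcommand,
    resolved_config = as.list(flatten_params(params)),
    genotype = if (!is.null(genotype)) format(parse_genotype(genotype)),
    seed = seed,
    package = "gqcycle",
    package_version = as.character(utils::packageVersion("gqcycle")),
    file_digests = as.list(vapply(files, digest_file, character(1))),
    wallclock_start = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    wallclock_end = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    extra = extra
  )
}

#' Write a manifest as JSON
#'
#' @param manifest a [run_manifest()] list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run a pipeline stage
#'
#' Programmatic entry point behind the command-line wrapper
#' (`inst/cli/gqcycle.R`). Writes the stage outputs (CSV + JSON) and a
#' manifest into `out_dir` and returns the main result invisibly.
#'
#' @param subcommand one of `"simulate"`, `"dose-response"`, `"sobol"`,
#'   `"classify"`, `"sweep-khyd2"`, `"enrichment"`, `"synth-cohort"`.
#' @param params a [gq_params()] object.
#' @param genotype genotype string (stages that use one).
#' @param out_dir output directory (created if needed).
#' @param seed top-level integer seed; every stochastic stage derives its
#'   randomness from it.
#' @param ... stage-specific options: `drug`, `grid` (dose-response);
#'   `ranges`, `n_base`, `n` (sobol/classify); `ratio_grid` (sweep);
#'   `inputs`, `mc_draws` (enrichment); `N`, `x`, `y`, `k` (synth-cohort).
#' @return the stage result, invisibly.
#' @export
gq_run <- function(subcommand, params = gq_params(), genotype = "WT",
                   out_dir = ".", seed = 1, ...) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "dose-response", "sobol", "classify",
                            "sweep-khyd2", "enrichment", "synth-cohort"))
  dots <- list(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()
  out_files <- character(0)
  result <- switch(
    subcommand,
    "simulate" = {
      tab <- simulate_genotypes(params, genotypes = dots$genotypes %||%
                                  format(parse_genotype(genotype)))
      f_csv <- file.path(out_dir, "steady_state.csv")
      utils::write.csv(tab, f_csv, row.names = FALSE)
      states <- purrr::map(tab$genotype, function(g) {
        as.list(solve_steady_state(params, g)$state)
      })
      names(states) <- tab$genotype
      f_json <- file.path(out_dir, "steady_state_species.json")
      jsonlite::write_json(states, f_json, auto_unbox = TRUE, digits = NA)
      out_files <- c(f_csv, f_json)
      tab
    },
    "dose-response" = {
      drug <- dots$drug %||% gq_drug()
      curve <- dose_response(params, genotype, drug = drug,
                             grid = dots$grid %||% dose_grid(drug))
      f_csv <- file.path(out_dir, "dose_response.csv")
      utils::write.csv(tibble::as_tibble(curve), f_csv, row.names = FALSE)
      f_json <- file.path(out_dir, "dose_response_summary.json")
      jsonlite::write_json(as.list(glance(curve)), f_json,
                           auto_unbox = TRUE, digits = NA)
      out_files <- c(f_csv, f_json)
      curve
    },
    "sobol" = {
      sens <- sensitivity_analysis(
        ranges = dots$ranges %||% default_ranges(), params = params,
        n_base = dots$n_base %||% 128, seed = seed
      )
      f_csv <- file.path(out_dir, "sobol_total.csv")
      utils::write.csv(tibble::as_tibble(sens), f_csv, row.names = FALSE)
      out_files <- f_csv
      sens
    },
    "classify" = {
      batch <- sample_parameter_sets(dots$ranges %||% default_ranges(),
                                     scheme = "lhs",
                                     n_base = dots$n %||% 2000, seed = seed)
      ev <- match_experiment(classify_behavior(
        evaluate_batch(batch, params = params)
      ))
      f_csv <- file.path(out_dir, "classified_batch.csv")
      utils::write.csv(tibble::as_tibble(ev), f_csv, row.names = FALSE)
      f_frac <- file.path(out_dir, "behavior_fractions.csv")
      utils::write.csv(behavior_fractions(ev), f_frac, row.names = FALSE)
      out_files <- c(f_csv, f_frac)
      ev
    },
    "sweep-khyd2" = {
      sw <- khyd2_sweep(params,
                        ratio_grid = dots$ratio_grid %||%
                          10^seq(-0.5, 3, length.out = 25))
      f_csv <- file.path(out_dir, "khyd2_sweep.csv")
      utils::write.csv(tibble::as_tibble(sw), f_csv, row.names = FALSE)
      out_files <- f_csv
      sw
    },
    "enrichment" = {
      inputs <- dots$inputs %||%
        enrichment_inputs(dots$N, dots$x, dots$y, dots$k)
      res <- enrichment_test(inputs, mc_draws = dots$mc_draws %||% 1e5,
                             seed = seed)
      f_json <- file.path(out_dir, "enrichment.json")
      jsonlite::write_json(as.list(tibble::as_tibble(res)), f_json,
                           auto_unbox = TRUE, digits = NA)
      out_files <- f_json
      res
    },
    "synth-cohort" = {
      coh <- make_cohort(dots$N, dots$x, dots$y, dots$k,
                         background_rate = dots$background_rate %||% 0.05,
                         seed = seed)
      f_tsv <- file.path(out_dir, "cohort.tsv")
      utils::write.table(tibble::as_tibble(coh), f_tsv, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      out_files <- f_tsv
      coh
    }
  )
  manifest <- run_manifest(subcommand, params, genotype = genotype,
                           seed = seed, files = out_files, started = started)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(result)
}
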