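#' Build an analysis configuration
#'
#' Collects every tunable of the two-arm analysis in one validated list.
#' Defaults follow the package's standard choices: raw mg/L trait scale, 999
#' permutations, Grafen power 1, chloride mg/L dose scale.
#'
#' @param tree_file Newick file with the species phylogeny.
#' @param trait_file Species-trait CSV (see [read_trait_csv()]).
#' @param mortality_file Mortality CSV (see [read_mortality_csv()]).
#' @param trait_scale `"raw"` or `"log10"` for the signal analyses.
#' @param groups Named list of species subsets, or `NULL` for
#'   [default_species_groups()].
#' @param n_perm Permutations for K and Mantel tests (>= 99).
#' @param seed Integer seed for all randomized steps.
#' @param rho Grafen power.
#' @param regrafen_after_prune Recompute Grafen lengths on pruned subtrees?
#' @param lc50_dose_scale `"chloride_mg_l"` (default) or `"salt_g_l"`: scale
#'   on which the LC50 GLMs are fitted.  Estimates are always reported in
#'   mg/L Cl.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(tree_file = NULL, trait_file = NULL,
                            mortality_file = NULL,
                            trait_scale = c("raw", "log10"), groups = NULL,
                            n_perm = 999, seed = 1, rho = 1,
                            regrafen_after_prune = FALSE,
                            lc50_dose_scale = c("chloride_mg_l", "salt_g_l"),
                            out_dir = NULL) {
  trait_scale <- match.arg(trait_scale)
  lc50_dose_scale <- match.arg(lc50_dose_scale)
  if (n_perm < 99) abort("n_perm must be at least 99.")
  if (!is.null(groups)) {
    if (is.null(names(groups)) || anyDuplicated(names(groups))) {
      abort("Group names must be unique.")
    }
  }
  for (f in c(tree_file, trait_file, mortality_file)) {
    if (!is.null(f) && !file.exists(f)) abort(sprintf("Input file not found: %s", f))
  }
  structure(
    list(
      tree_file = tree_file, trait_file = trait_file,
      mortality_file = mortality_file, trait_scale = trait_scale,
      groups = groups, n_perm = as.integer(n_perm), seed = as.integer(seed),
      rho = rho, regrafen_after_prune = isTRUE(regrafen_after_prune),
      lc50_dose_scale = lc50_dose_scale, out_dir = out_dir
    ),
    class = "analysis_config"
  )
}

#' Read a flat key=value configuration file
#'
#' One `key = value` per line, `#` comments allowed.  Recognized keys are the
#' scalar arguments of [analysis_config()]; unknown keys raise an error.
#' Group definitions are code-level (pass `groups` to [analysis_config()] or
#' rely on the defaults).
#'
#' @param path Path to the config file.
#' @param ... Overrides applied after the file (highest precedence).
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[lengths(kv) != 2]
  if (length(bad)) abort(sprintf("Malformed config line: '%s'", bad[1]))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  allowed <- c(
    "tree_file", "trait_file", "mortality_file", "trait_scale", "n_perm",
    "seed", "rho", "regrafen_after_prune", "lc50_dose_scale", "out_dir"
  )
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  args <- as.list(setNames(vals, keys))
  for (k in c("n_perm", "seed", "rho")) {
    if (k %in% names(args)) args[[k]] <- as.numeric(args[[k]])
  }
  if ("regrafen_after_prune" %in% names(args)) {
    args$regrafen_after_prune <- tolower(args$regrafen_after_prune) %in% c("true", "1", "yes")
  }
  args <- modifyList(args, list(...))
  do.call(analysis_config, args)
}

cl_per_nacl <- 1000 * 35.453 / 58.443 # mg Cl per g NaCl

#' Run the macroevolutionary (phylogenetic-signal) analysis
#'
#' End to end: read tree and trait CSV, aggregate to one LC50 per species,
#' test for an exposure-duration effect, assign Grafen branch lengths when
#' the tree has none, and run the per-group signal suite (lambda, K, Mantel).
#'
#' @param config An [analysis_config()] with `tree_file` and `trait_file`
#'   set.
#' @return List of class `macro_report`: `signal` (per-group tibble),
#'   `duration_test`, `species_values`, `dropped_species`, `skipped_groups`,
#'   `config`.
#' @export
run_macro_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$tree_file) || is.null(config$trait_file)) {
    abort("config must set tree_file and trait_file.")
  }
  tree <- parse_newick(paste(readLines(config$tree_file, warn = FALSE), collapse = ""))
  records <- read_trait_csv(config$trait_file)
  sv <- aggregate_species(records)
  overlap <- intersect(sv$species, tree$tip.label)
  if (length(overlap) < 4) {
    abort(sprintf(
      "Only %d species shared between tree and trait table (need >= 4).",
      length(overlap)
    ))
  }
  if (length(unique(records$duration_h)) >= 2) {
    dur <- duration_effect_test(records, trait_scale = config$trait_scale)
  } else {
    inform("Single exposure duration in the trait table; duration F test not applicable.")
    dur <- tibble::tibble(
      statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
      p_value = NA_real_, n_groups = 1L, n_obs = nrow(records)
    )
  }
  if (is.null(tree$edge.length)) tree <- grafen_branch_lengths(tree, rho = config$rho)
  groups <- config$groups %||% default_species_groups(sv)
  signal <- run_signal_suite(
    sv, tree,
    groups = groups, n_perm = config$n_perm, seed = config$seed,
    trait_scale = config$trait_scale,
    regrafen_after_prune = config$regrafen_after_prune, rho = config$rho
  )
  structure(
    list(
      signal = signal,
      duration_test = dur,
      species_values = sv,
      dropped_species = attr(signal, "dropped_species"),
      skipped_groups = attr(signal, "skipped"),
      config = config
    ),
    class = "macro_report"
  )
}

#' Run the population-level (acute-toxicity) analysis
#'
#' Fits the logit-binomial mixed model on the full mortality table to test
#' the concentration x population-type interaction, then fits a plain
#' binomial GLM per population type (ponds pooled within type) and derives
#' each type's LC50 with a delta-method 95% interval.
#'
#' @param config An [analysis_config()] with `mortality_file` set, or a
#'   mortality tibble.
#' @return List of class `toxicity_report`: `lc50` (two-row tibble), `glmm`
#'   (`tox_glmm`), `interaction`, `config`.
#' @export
run_toxicity_pipeline <- function(config) {
  if (inherits(config, "analysis_config")) {
    if (is.null(config$mortality_file)) abort("config must set mortality_file.")
    data <- read_mortality_csv(config$mortality_file)
    dose_scale <- config$lc50_dose_scale
  } else {
    data <- validate_mortality(config)
    dose_scale <- "chloride_mg_l"
    config <- analysis_config()
  }
  if (length(unique(data$type)) < 2) {
    abort("Both population types (roadside, woodland) must be present.")
  }
  glmm <- fit_glmm_laplace(data)
  fit_one <- function(ty) {
    d <- dplyr::filter(data, .data$type == ty)
    if (dose_scale == "salt_g_l") {
      d$conc_mg_l <- d$conc_mg_l / cl_per_nacl
    }
    fit <- fit_binomial_glm(d, predictors = ~conc_mg_l)
    est <- estimate_lc50(fit, population_label = ty)
    if (dose_scale == "salt_g_l") {
      est <- dplyr::mutate(est, dplyr::across(
        c("lc50", "se", "ci_low", "ci_high"), ~ .x * cl_per_nacl
      ))
    }
    est
  }
  lc50 <- dplyr::bind_rows(lapply(sort(unique(data$type)), fit_one))
  structure(
    list(
      lc50 = lc50,
      glmm = glmm,
      interaction = glmm$interaction,
      config = config
    ),
    class = "toxicity_report"
  )
}

#' Run both analysis arms and write the report artifacts
#'
#' Runs [run_macro_pipeline()] and/or [run_toxicity_pipeline()] depending on
#' which inputs the config names, and writes `signal_results.csv`,
#' `lc50_results.csv`, `glmm_summary.json`, `report.json` and `run.log` into
#' `config$out_dir`.  The report body is deterministic for a fixed config and
#' inputs; timestamps appear only in the log.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the `macro` and `toxicity` reports and the
#'   vector of files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$out_dir)) abort("config must set out_dir.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  macro <- NULL
  toxicity <- NULL
  log_lines <- c(
    sprintf("phylotox %s", as.character(utils::packageVersion("phylotox"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d  n_perm: %d", config$seed, config$n_perm),
    sprintf("trait_scale: %s  lc50_dose_scale: %s", config$trait_scale, config$lc50_dose_scale)
  )
  files <- character(0)
  if (!is.null(config$tree_file) && !is.null(config$trait_file)) {
    macro <- run_macro_pipeline(config)
    f <- file.path(config$out_dir, "signal_results.csv")
    readr::write_csv(macro$signal, f)
    files <- c(files, f)
    if (length(macro$dropped_species)) {
      log_lines <- c(log_lines, sprintf(
        "dropped species (not in tree): %s",
        paste(macro$dropped_species, collapse = ", ")
      ))
    }
    if (length(macro$skipped_groups)) {
      log_lines <- c(log_lines, sprintf(
        "skipped groups (< 4 species): %s",
        paste(macro$skipped_groups, collapse = ", ")
      ))
    }
  }
  if (!is.null(config$mortality_file)) {
    toxicity <- run_toxicity_pipeline(config)
    f <- file.path(config$out_dir, "lc50_results.csv")
    readr::write_csv(toxicity$lc50, f)
    files <- c(files, f)
    g <- file.path(config$out_dir, "glmm_summary.json")
    jsonlite::write_json(
      list(
        fixed_effects = toxicity$glmm$fixed_effects,
        sigma = as.list(toxicity$glmm$sigma),
        log_lik = toxicity$glmm$log_lik,
        aic = toxicity$glmm$aic,
        boundary = toxicity$glmm$boundary_flag,
        interaction = toxicity$glmm$interaction
      ),
      g,
      auto_unbox = TRUE, digits = NA
    )
    files <- c(files, g)
  }
  report <- list(
    provenance = list(
      version = as.character(utils::packageVersion("phylotox")),
      seed = config$seed, n_perm = config$n_perm,
      trait_scale = config$trait_scale,
      lc50_dose_scale = config$lc50_dose_scale,
      rho = config$rho,
      regrafen_after_prune = config$regrafen_after_prune,
      dropped_species = macro$dropped_species %||% character(0),
      skipped_groups = macro$skipped_groups %||% character(0)
    ),
    signal = macro$signal,
    duration_test = macro$duration_test,
    lc50 = toxicity$lc50,
    interaction = toxicity$interaction
  )
  f <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)
  logf <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, logf)
  files <- c(files, logf)
  invisible(list(macro = macro, toxicity = toxicity, files = files))
}
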