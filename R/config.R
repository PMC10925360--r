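# JSON analysis configuration and result export.

.CONFIG_KEYS <- c("sumstats", "ld_reference", "out_dir",
                  "maf_thresh", "info_thresh", "z_thresh",
                  "exclude_regions", "do_pruning", "r2_prune_thresh",
                  "n_random", "rand_prune_seed",
                  "grid_step", "grid_half_width", "grid_points_3d",
                  "deviation_metric")

#' Load a JSON analysis configuration
#'
#' Unknown keys are rejected; absent optional keys fall back to the
#' conventional defaults (`maf_thresh` 0.05, `info_thresh` 0.8, `z_thresh`
#' 32, MHC exclusion, pruning at r2 0.8, 500,000 template variants,
#' `rand_prune_seed` 1).  `rand_prune_seed` may be a list of seeds, one
#' optimization run each.
#'
#' @param path Path to the JSON file.
#' @param check_paths Verify that the referenced sumstats/reference paths
#'   exist (default `TRUE`).
#' @return Object of class `analysis_config`: the [qc_config()] fields plus
#'   `sumstats` (three paths), `ld_reference`, `out_dir`,
#'   `deviation_metric` and grid settings.
#' @export
load_config <- function(path, check_paths = TRUE) {
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e))
                  })
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(maf_thresh = 0.05, info_thresh = 0.8, z_thresh = 32,
                   exclude_regions = "6:25000000-34000000",
                   do_pruning = TRUE, r2_prune_thresh = 0.8,
                   n_random = 500000, rand_prune_seed = 1L,
                   out_dir = ".", deviation_metric = "euclidean",
                   grid_step = NULL, grid_half_width = 12,
                   grid_points_3d = 33)
  cfg <- modifyList(defaults, cfg, keep.null = TRUE)
  num_keys <- c("maf_thresh", "info_thresh", "z_thresh", "r2_prune_thresh",
                "n_random", "grid_half_width", "grid_points_3d")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || !all(is.finite(cfg[[k]]))) {
      stop("configuration key '", k, "' must be numeric")
    }
  }
  if (!is.logical(cfg$do_pruning)) {
    stop("configuration key 'do_pruning' must be true/false")
  }
  if (!is.numeric(cfg$rand_prune_seed)) {
    stop("configuration key 'rand_prune_seed' must be numeric")
  }
  if (anyDuplicated(cfg$rand_prune_seed)) {
    stop("rand_prune_seed values must be unique")
  }
  if (!is.null(cfg$sumstats)) {
    if (length(cfg$sumstats) != 3L) {
      stop("configuration must name exactly three sumstats files")
    }
    if (check_paths) {
      miss <- cfg$sumstats[!file.exists(cfg$sumstats)]
      if (!is.null(cfg$ld_reference) && !file.exists(cfg$ld_reference)) {
        miss <- c(miss, cfg$ld_reference)
      }
      if (length(miss)) {
        stop("configured path(s) do not exist: ",
             paste(miss, collapse = ", "))
      }
    }
  }
  structure(cfg, class = "analysis_config")
}

#' @rdname load_config
#' @param config An `analysis_config`.
#' @return `as_qc_config()`: the embedded [qc_config()].
#' @export
as_qc_config <- function(config) {
  qc_config(maf_thresh = config$maf_thresh,
            info_thresh = config$info_thresh, z_thresh = config$z_thresh,
            exclude_regions = config$exclude_regions,
            do_pruning = config$do_pruning,
            r2_prune_thresh = config$r2_prune_thresh,
            n_random = config$n_random,
            rand_prune_seed = config$rand_prune_seed)
}

# Euler area-specification lines for the seven regions, eulerr-style labels
.euler_spec_lines <- function(pattern, labels = c("T1", "T2", "T3")) {
  m <- unclass(pattern)
  keys <- c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23", "pi123")
  combos <- list(labels[1], labels[2], labels[3],
                 labels[c(1, 2)], labels[c(1, 3)], labels[c(2, 3)], labels)
  vapply(seq_along(keys), function(i) {
    sprintf("%s\t%.10g", paste(combos[[i]], collapse = "&"), m[keys[i]])
  }, "")
}

#' Export fit results, summaries and the Euler area specification
#'
#' Writes (a) one JSON per run with all 19 parameters, objectives and
#' diagnostics; (b) a summary JSON with the median pattern, the
#' representative run's pattern, the naive maximum-entropy pattern and both
#' percentage tables -- each computed against the representative pattern's
#' combined total, so the naive percentages need not sum to 100; and (c) a
#' tab-separated Euler area specification (region label -> mass) consumable
#' by external area-proportional diagram renderers.
#'
#' @param runs A list of `mix_run` objects.
#' @param selection Result of [select_representative()] on `runs`.
#' @param naive Result of [max_entropy_tri_overlap()] for the fitted
#'   marginals.
#' @param out_dir Output directory (created if needed).
#' @param labels Phenotype labels used in the Euler specification.
#' @return Invisible character vector of the files written.
#' @export
export_results <- function(runs, selection, naive, out_dir,
                           labels = c("T1", "T2", "T3")) {
  if (!length(runs)) stop("no runs to export")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  files <- character(0)
  flat_params <- function(p) {
    list(pi1u = p$uni[[1]]$pi_u, pi2u = p$uni[[2]]$pi_u,
         pi3u = p$uni[[3]]$pi_u,
         sigma1_sq = p$uni[[1]]$sigma_beta_sq,
         sigma2_sq = p$uni[[2]]$sigma_beta_sq,
         sigma3_sq = p$uni[[3]]$sigma_beta_sq,
         sigma01_sq = p$uni[[1]]$sigma0_sq,
         sigma02_sq = p$uni[[2]]$sigma0_sq,
         sigma03_sq = p$uni[[3]]$sigma0_sq,
         pi12b = p$pairs[[1]]$pi_b, pi13b = p$pairs[[2]]$pi_b,
         pi23b = p$pairs[[3]]$pi_b,
         rho12 = p$pairs[[1]]$rho, rho13 = p$pairs[[2]]$rho,
         rho23 = p$pairs[[3]]$rho,
         rho012 = p$pairs[[1]]$rho0, rho013 = p$pairs[[2]]$rho0,
         rho023 = p$pairs[[3]]$rho0,
         pi123 = p$pi123)
  }
  for (r in runs) {
    f <- file.path(out_dir, sprintf("run_seed%s.json", r$seed))
    jsonlite::write_json(
      list(seed = r$seed, parameters = flat_params(r$params),
           pattern = as.list(unclass(r$pattern)),
           objectives = r$objectives, diagnostics = r$diagnostics),
      f, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    files <- c(files, f)
  }
  rep_pat <- selection$representative$pattern
  total <- pattern_total(rep_pat)
  summary <- list(
    median_pattern = as.list(selection$median_pattern),
    median_feasible = selection$median_feasible,
    representative_seed = selection$representative$seed,
    representative_pattern = as.list(unclass(rep_pat)),
    naive_pattern = as.list(unclass(naive$pattern)),
    pi123_naive = naive$pi123_naive,
    percentages_model = as.list(pattern_percentages(rep_pat, total)),
    percentages_naive = as.list(pattern_percentages(naive$pattern, total)))
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- file.path(out_dir, "euler_areas.tsv")
  writeLines(.euler_spec_lines(rep_pat, labels), f)
  files <- c(files, f)
  invisible(files)
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads and harmonizes the three summary-statistics files against the LD
#' reference, applies quality control, executes one stepwise fit per
#' configured seed, selects the representative run, computes the naive
#' maximum-entropy expectation from the fitted marginals and exports all
#' results to `out_dir`.
#'
#' @param config An `analysis_config` from [load_config()].
#' @param grids,options Passed to [fit_triad()].
#' @return List with `runs`, `selection`, `naive` and `files`.
#' @export
run_pipeline <- function(config, grids = NULL, options = fit_options()) {
  reference <- load_reference(config$ld_reference)
  harmonized <- harmonize_sumstats(as.list(config$sumstats), reference)
  qc <- as_qc_config(config)
  filtered <- qc_filter(harmonized, qc, reference)
  runs <- multi_run(filtered, reference, qc,
                    seeds = config$rand_prune_seed, grids = grids,
                    options = options)
  selection <- select_representative(runs, config$deviation_metric)
  rep_params <- selection$representative$params
  naive <- max_entropy_tri_overlap(
    vapply(rep_params$uni, `[[`, 0, "pi_u"),
    vapply(rep_params$pairs, `[[`, 0, "pi_b"))
  files <- export_results(runs, selection, naive, config$out_dir)
  list(runs = runs, selection = selection, naive = naive, files = files)
}
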