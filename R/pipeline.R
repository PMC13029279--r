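# End-to-end orchestration: one configuration object, stages executed in
# dependency order, every output table written as delimited text, and a
# machine-readable run manifest carrying the configuration hash and seeds.

#' Pipeline run configuration
#'
#' Bundles the inputs (a synthetic-cohort configuration, or paths to
#' existing input tables), per-stage seeds and the analysis thresholds.
#'
#' @param out_dir Output directory for the run's artifacts.
#' @param synth A [synth_config()] to simulate inputs, or `NULL` when
#'   `input_paths` are supplied.
#' @param input_paths Named list of paths (`cases`, `catalog`, `admet`,
#'   `pk_bounds`, `potency`) used when `synth` is `NULL`.
#' @param harmonise_threshold Phenotype collapse threshold (default 0.02).
#' @param fdr FDR threshold for the enriched flag (default 0.05).
#' @param mvi_weights Composite weights for [composite_raw()].
#' @param dps_thresholds Absolute DPS tier thresholds.
#' @param mc_n Monte Carlo samples per exposure ratio.
#' @param robustness_depths,robustness_replicates Hub-removal settings.
#' @param seed Master seed; each stochastic stage receives a derived
#'   sub-seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synth = NULL,
                       input_paths = NULL,
                       harmonise_threshold = 0.02,
                       fdr = 0.05,
                       mvi_weights = c(0.60, 0.15, 0.15, 0.10),
                       dps_thresholds = c(high = 0.75, moderate = 0.50),
                       mc_n = 10000,
                       robustness_depths = 0:10,
                       robustness_replicates = 200,
                       seed = 1L) {
  if (is.null(synth) && is.null(input_paths)) {
    abort("Provide either a `synth` configuration or `input_paths`.")
  }
  stopifnot(harmonise_threshold > 0, harmonise_threshold < 1,
            fdr > 0, fdr < 1, mc_n >= 1)
  structure(list(out_dir = out_dir, synth = synth, input_paths = input_paths,
                 harmonise_threshold = harmonise_threshold, fdr = fdr,
                 mvi_weights = mvi_weights, dps_thresholds = dps_thresholds,
                 mc_n = mc_n, robustness_depths = robustness_depths,
                 robustness_replicates = robustness_replicates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — synthetic data (or ingestion),
#' case model, phenotypes, enrichment, network, seriousness regression,
#' scoring, exposure-liability, embedding — writing each stage's output
#' tables under `out_dir` and a JSON manifest listing all stage outputs,
#' the configuration hash and the seeds used. Re-running with the same
#' configuration reproduces identical tables.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6, salt = 55L)
  hashable <- unclass(config)
  hashable$out_dir <- NULL # the analysis identity is path-independent
  manifest <- list(config_hash = rlang::hash(hashable),
                   seed = config$seed, stages = list())
  path <- function(f) file.path(config$out_dir, f)
  emit <- function(stage, tbl, file) {
    readr::write_csv(tbl, path(file))
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], file)
  }

  # -- inputs: simulate or ingest ------------------------------------------
  if (!is.null(config$synth)) {
    cohort <- generate_cohort(config$synth)
    admet <- generate_admet_table(cohort$catalog,
                                  shifts = config$synth$admet_shift_matrix,
                                  missing_frac = config$synth$admet_missing_frac,
                                  noise_sd = config$synth$admet_noise_sd,
                                  seed = seeds[1])
    pk <- generate_pk_tables(cohort$catalog, seed = seeds[1])
    files <- write_synthetic_inputs(cohort, admet, pk, config$out_dir)
    manifest$stages[["synthetic_data"]] <- unname(basename(files))
    cases <- cohort$cases
    catalog <- cohort$catalog
  } else {
    p <- config$input_paths
    for (key in c("cases", "catalog", "admet")) {
      if (is.null(p[[key]]) || !file.exists(p[[key]])) {
        abort(sprintf("Input '%s' is required but missing%s.", key,
                      if (is.null(p[[key]])) "" else paste0(" at ", p[[key]])))
      }
    }
    cases <- read_cases(p$cases)
    catalog <- readr::read_csv(p$catalog, show_col_types = FALSE)
    admet <- readr::read_csv(p$admet, show_col_types = FALSE)
    pk <- list(
      pk_bounds = if (!is.null(p$pk_bounds)) readr::read_csv(p$pk_bounds, show_col_types = FALSE),
      potency = if (!is.null(p$potency)) readr::read_csv(p$potency, show_col_types = FALSE)
    )
    manifest$stages[["synthetic_data"]] <- character(0)
  }

  # -- case model -----------------------------------------------------------
  expanded <- suppressMessages(expand_cases(cases))
  poly <- compute_polypharmacy(cases)
  emit("icsr", expanded, "expanded.csv")
  emit("icsr", poly, "polypharmacy.csv")

  # -- phenotypes -----------------------------------------------------------
  map <- harmonise_phenotypes(cases, config$harmonise_threshold)
  sev <- seriousness_by_phenotype(cases, map)
  sig <- suppressMessages(admet_signature(expanded, admet, map))
  kw <- suppressMessages(kw_panel(expanded, admet, map))
  emit("phenotypes", tibble::as_tibble(map), "phenotype_map.csv")
  emit("phenotypes", sev, "phenotype_seriousness.csv")
  emit("phenotypes", signature_tidy(sig), "admet_signature.csv")
  emit("phenotypes", kw, "kw_panel.csv")

  # -- enrichment -----------------------------------------------------------
  enr_primary <- suppressMessages(
    enrichment_panel(cases, map, catalog, "primary", fdr = config$fdr))
  enr_all <- suppressMessages(
    enrichment_panel(cases, map, catalog, "all_suspect", fdr = config$fdr))
  jac <- suppressMessages(attribution_sensitivity(enr_primary, enr_all))
  emit("enrichment", enr_primary, "enrichment_primary.csv")
  emit("enrichment", enr_all, "enrichment_all_suspect.csv")
  emit("enrichment", jac, "attribution_jaccard.csv")

  # -- network --------------------------------------------------------------
  graph <- build_comed_graph(cases)
  cent <- node_centrality(graph)
  depths <- config$robustness_depths
  depths <- depths[depths <= igraph::vcount(graph) - 1]
  rob <- robustness_sim(graph, depths = depths,
                        replicates = config$robustness_replicates,
                        seed = seeds[2])
  write_edge_list(graph, path("comed_edges.csv"))
  manifest$stages[["network"]] <- "comed_edges.csv"
  emit("network", cent, "centrality.csv")
  emit("network", rob, "robustness.csv")

  # -- seriousness regression ----------------------------------------------
  fit <- fit_seriousness(cases)
  restricted <- sensitivity_restrict(cases)
  fits <- tibble::tibble(
    specification = c(fit$specification, "restricted (female, non-follow-up, non-literature)"),
    or_per_active = c(fit$or_per_active, restricted$fit$or_per_active),
    ci_lo = c(fit$ci_lo, restricted$fit$ci_lo),
    ci_hi = c(fit$ci_hi, restricted$fit$ci_hi),
    p = c(fit$p, restricted$fit$p),
    n = c(fit$n, restricted$fit$n)
  )
  emit("seriousness", fits, "seriousness_fits.csv")

  # -- scoring --------------------------------------------------------------
  mvi <- mvi_table(cases, map, graph, admet, weights = config$mvi_weights,
                   seed = seeds[3])
  regimens <- derive_regimens(cases)
  dps <- if (nrow(regimens)) {
    dps_table(regimens, admet, cent, mvi, thresholds = config$dps_thresholds)
  } else {
    tibble::tibble()
  }
  emit("scoring", mvi, "mvi.csv")
  emit("scoring", dps, "dps.csv")

  # -- exposure-liability ---------------------------------------------------
  ratios <- if (!is.null(pk$pk_bounds) && nrow(pk$pk_bounds)) {
    exposure_liability_panel(pk$pk_bounds, pk$potency, n = config$mc_n,
                             seed = seeds[4])
  } else {
    tibble::tibble()
  }
  emit("exposure", ratios, "exposure_ratios.csv")

  # -- embedding ------------------------------------------------------------
  summ <- drug_level_summary(cases, map, graph)
  feats <- embedding_features(summ, admet)
  emb <- suppressMessages(pca_embed(zscore_features(feats)))
  loadings <- tibble::as_tibble(emb$loadings, rownames = "feature")
  scores <- tibble::as_tibble(emb$scores, rownames = "drug") |>
    dplyr::left_join(summ[c("drug", "dominant_phenotype")], by = "drug")
  emit("embedding", loadings, "pca_loadings.csv")
  emit("embedding", scores, "pca_scores.csv")
  emit("embedding",
       tibble::tibble(component = paste0("PC", seq_along(emb$variance_frac_all)),
                      variance_frac = emb$variance_frac_all),
       "pca_variance.csv")

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
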