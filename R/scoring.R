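# Drug-level mechanistic vulnerability index (MVI) and regimen-level
# drug-drug interaction prioritisation score (DPS).
#
# The MVI chain: an empirical burden proxy (reporting volume x phenotypic
# breadth), a high-burden label at the upper quartile, a random-forest
# probability of high burden from mechanistic/system-level features, a
# weighted composite with standardised polypharmacy / network / severity
# components, and a 0-100 percentile transform.

percent_rank01 <- function(x) {
  n <- length(x)
  if (n == 1) {
    warn("Single observation: percent rank defined as 1.")
    return(1)
  }
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Empirical ADR burden composite
#'
#' Product of reporting volume and phenotypic breadth per drug.
#' @param total_reports,n_clusters Non-negative integer vectors.
#' @return Numeric vector `total_reports * n_clusters`.
#' @export
adr_composite <- function(total_reports, n_clusters) {
  stopifnot(all(total_reports >= 0), all(n_clusters >= 0))
  total_reports * n_clusters
}

#' Label high-burden drugs at the upper quartile
#'
#' `TRUE` iff the value is at or above the 0.75 quantile of the empirical
#' burden distribution, computed with linear-interpolation (type 7)
#' quantiles. Requires at least 4 drugs.
#' @param values Numeric burden values (one per drug).
#' @return Logical vector.
#' @export
label_high_burden <- function(values) {
  if (length(values) < 4) abort("High-burden labelling requires at least 4 drugs.")
  q <- quantile(values, 0.75, type = 7, names = FALSE)
  values >= q
}

# Median-impute missing values column-wise in a numeric matrix/data frame.
median_impute <- function(x) {
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (anyNA(v)) {
      v[is.na(v)] <- median(v, na.rm = TRUE)
      x[[j]] <- v
    }
  }
  x
}

#' Random-forest probability of high empirical burden
#'
#' Trains a probability random forest on drug-level features and returns the
#' out-of-bag probability of the high-burden class for each drug (in-bag
#' refit probability for any drug never out of bag). Missing predictor
#' values are median-imputed within columns before fitting. Features named
#' in `exclude` are dropped; the default excludes the constituents of the
#' label (`total_reports`, `n_clusters`) to avoid leakage, with the
#' inclusive variant available by passing `exclude = character(0)`.
#'
#' @param features Tibble with a `drug` column plus numeric feature columns.
#' @param labels Logical high-burden labels, one per row of `features`.
#' @param seed Integer seed (forest growth is deterministic per seed).
#' @param n_trees Number of trees.
#' @param exclude Feature names to drop before fitting.
#' @return Tibble `drug`, `rf_prob`; attributes `model` (the ranger fit),
#'   `oob_error` (OOB misclassification at 0.5) and `feature_names`.
#' @export
fit_rf_high_burden <- function(features, labels, seed = 1L, n_trees = 500,
                               exclude = c("total_reports", "n_clusters")) {
  if (length(unique(labels)) < 2) {
    abort("Both high-burden classes must be present to fit the classifier.")
  }
  x <- features[setdiff(names(features), c("drug", exclude))]
  x <- median_impute(x)
  df <- data.frame(.y = factor(labels, levels = c(FALSE, TRUE)), x,
                   check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = n_trees, seed = seed, respect.unordered.factors = "order"
  )
  prob <- fit$predictions[, "TRUE"]
  if (anyNA(prob)) {
    inbag <- predict(fit, data = df)$predictions[, "TRUE"]
    prob[is.na(prob)] <- inbag[is.na(prob)]
  }
  oob_err <- mean((prob > 0.5) != labels)
  structure(tibble::tibble(drug = features$drug, rf_prob = unname(prob)),
            model = fit, oob_error = oob_err, feature_names = names(x))
}

#' Composite raw vulnerability score
#'
#' Weighted combination of the predicted high-burden probability and
#' standardised system-level components:
#' `0.60 P + 0.15 z_poly + 0.15 z_net + 0.10 z_sev` by default.
#'
#' @param rf_prob Predicted high-burden probability.
#' @param z_poly,z_net,z_sev Standardised polypharmacy, network and
#'   severity components.
#' @param weights Non-negative weights summing to 1, in the order
#'   (probability, polypharmacy, network, severity).
#' @return Numeric composite score vector.
#' @export
composite_raw <- function(rf_prob, z_poly, z_net, z_sev,
                          weights = c(0.60, 0.15, 0.15, 0.10)) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be non-negative and sum to 1.")
  }
  weights[1] * rf_prob + weights[2] * z_poly + weights[3] * z_net +
    weights[4] * z_sev
}

#' Percentile-scale MVI
#'
#' Maps composite raw scores to a 0-100 percentile scale with the
#' `(rank - 1) / (n - 1)` percent-rank convention (average ranks for ties):
#' the top drug scores 100.0, the bottom 0.0, and with 25 tie-free drugs
#' consecutive ranks differ by 100/24.
#' @param scores Composite raw scores (>= 2 drugs; a single drug is defined
#'   as 100 with a warning).
#' @return Numeric vector on 0-100.
#' @export
mvi_percentile <- function(scores) {
  100 * percent_rank01(scores)
}

#' Drug-level summary table
#'
#' Per-drug aggregates feeding the MVI: case-level reporting volume (cases
#' in which the drug is a suspect), expanded-record volume, phenotypic
#' breadth (distinct harmonised phenotypes), dominant phenotype, serious
#' report fraction, mean per-report polypharmacy, and co-medication network
#' degree/betweenness of the drug's node.
#'
#' @param cases Case-level tibble.
#' @param map Phenotype map.
#' @param graph Co-medication graph (from [build_comed_graph()]).
#' @param drugs Drugs to summarise (default: all suspect drugs observed).
#' @param sep Intra-cell separator.
#' @return Tibble, one row per drug.
#' @export
drug_level_summary <- function(cases, map, graph, drugs = NULL, sep = ";") {
  cc <- apply_phenotype_map(cases, map)
  poly <- compute_polypharmacy(cc, sep = sep)
  long <- cc |>
    dplyr::transmute(case_id = .data$case_id, drug = .data$suspect_actives,
                     phenotype = .data$phenotype, serious = .data$serious,
                     n_react = vapply(.data$reactions,
                                      function(r) length(split_cell(r, sep)),
                                      integer(1), USE.NAMES = FALSE)) |>
    tidyr::separate_rows("drug", sep = sep) |>
    dplyr::left_join(poly[c("case_id", "poly_actives_total")], by = "case_id")
  if (!is.null(drugs)) long <- long[long$drug %in% drugs, ]
  cent <- node_centrality(graph)
  out <- long |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      total_reports = dplyr::n_distinct(.data$case_id),
      expanded_reports = sum(.data$n_react),
      n_clusters = dplyr::n_distinct(.data$phenotype),
      dominant_phenotype = names(sort(table(.data$phenotype), decreasing = TRUE))[1],
      serious_frac = mean(.data$serious),
      mean_polypharmacy = mean(.data$poly_actives_total),
      .groups = "drop"
    ) |>
    dplyr::left_join(cent, by = "drug")
  out$degree[is.na(out$degree)] <- 0
  out$betweenness[is.na(out$betweenness)] <- 0
  out
}

#' Mechanistic vulnerability index table
#'
#' Runs the full MVI chain for every suspect drug: burden composite,
#' upper-quartile high-burden label, random-forest high-burden probability
#' (from mean polypharmacy, network degree/betweenness, serious fraction and
#' available continuous ADMET predictors), standardised components
#' (`z_poly` = z of mean per-report active count; `z_net` = mean of
#' z(degree) and z(betweenness); `z_sev` = z of the serious-report
#' fraction), the weighted composite and the percentile MVI.
#'
#' @inheritParams drug_level_summary
#' @param admet ADMET table (joined by drug; missing drugs are imputed).
#' @param weights Composite weights, see [composite_raw()].
#' @param seed Integer seed for the forest.
#' @param exclude Features excluded from the forest (see
#'   [fit_rf_high_burden()]).
#' @return Tibble of MVI records (one per drug) with attributes `rf`
#'   (the fitted probability table) and `features`.
#' @export
mvi_table <- function(cases, map, graph, admet, drugs = NULL,
                      weights = c(0.60, 0.15, 0.15, 0.10), seed = 1L,
                      exclude = c("total_reports", "n_clusters"), sep = ";") {
  summ <- drug_level_summary(cases, map, graph, drugs = drugs, sep = sep)
  summ$adr_composite <- adr_composite(summ$total_reports, summ$n_clusters)
  summ$high_burden <- label_high_burden(summ$adr_composite)
  feat_cols <- intersect(ADMET_CONTINUOUS, names(admet))
  features <- summ[c("drug", "total_reports", "n_clusters", "mean_polypharmacy",
                     "degree", "betweenness", "serious_frac")] |>
    dplyr::left_join(admet[c("drug", feat_cols)], by = "drug")
  rf <- fit_rf_high_burden(features, summ$high_burden, seed = seed,
                           exclude = exclude)
  z_poly <- zscore(summ$mean_polypharmacy)
  z_net <- (zscore(summ$degree) + zscore(summ$betweenness)) / 2
  z_sev <- zscore(summ$serious_frac)
  comp <- composite_raw(rf$rf_prob, z_poly, z_net, z_sev, weights = weights)
  out <- tibble::tibble(
    drug = summ$drug,
    total_reports = summ$total_reports,
    expanded_reports = summ$expanded_reports,
    n_clusters = summ$n_clusters,
    dominant_phenotype = summ$dominant_phenotype,
    adr_composite = summ$adr_composite,
    high_burden = summ$high_burden,
    rf_prob = rf$rf_prob,
    serious_frac = summ$serious_frac,
    mean_polypharmacy = summ$mean_polypharmacy,
    degree = summ$degree,
    betweenness = summ$betweenness,
    z_poly = z_poly, z_net = z_net, z_sev = z_sev,
    composite_raw = comp,
    mvi_pct = mvi_percentile(comp)
  )
  structure(out, rf = rf, features = features, weights = weights, seed = seed)
}

# Variance inflation factors for a numeric component matrix.
vif_components <- function(x) {
  x <- as.data.frame(x)
  vapply(names(x), function(col) {
    r2 <- summary(lm(as.formula(paste0("`", col, "` ~ .")), data = x))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Robustness diagnostics for the MVI machine-learning component
#'
#' Computes, each under its own sub-seed derived from `seed`: a stratified
#' 70/30 hold-out AUC, leave-one-drug-out AUC, out-of-bag error, bootstrap
#' percentile intervals of the predicted probabilities (B refits),
#' importance coefficient-of-variation across bootstrap refits, rank
#' correlations (Spearman, Kendall) between the default-weight and
#' alternative-weight MVI rankings, and variance inflation factors of the
#' four composite components.
#'
#' @param mvi Result of [mvi_table()].
#' @param B Bootstrap replicates (default 500; must be >= 2).
#' @param alt_weights Alternative composite weights for the rank-stability
#'   check.
#' @param seed Integer seed.
#' @param n_trees Trees per forest refit.
#' @return List with `holdout_auc`, `lodo_auc`, `oob_error`,
#'   `bootstrap` (per-drug CI tibble plus width summaries),
#'   `importance_cv`, `weight_rank_stability`, `vif`.
#' @export
mvi_diagnostics <- function(mvi, B = 500, alt_weights = c(0.40, 0.20, 0.20, 0.20),
                            seed = 1L, n_trees = 500) {
  if (B < 2) abort("`B` must be at least 2.")
  features <- attr(mvi, "features")
  labels <- mvi$high_burden
  exclude <- setdiff(names(features),
                     c("drug", attr(attr(mvi, "rf"), "feature_names")))
  n <- nrow(features)
  if (n < 10) abort("Hold-out diagnostics require at least 10 drugs.")
  seeds <- derive_seeds(seed, 4 + B, salt = 31L)
  refit_prob <- function(train_idx, predict_idx, s) {
    sub <- fit_rf_high_burden(features[train_idx, ], labels[train_idx],
                              seed = s, n_trees = n_trees, exclude = exclude)
    fit <- attr(sub, "model")
    x <- median_impute(features[setdiff(names(features), c("drug", exclude))])
    predict(fit, data = as.data.frame(x[predict_idx, ]))$predictions[, "TRUE"]
  }
  # 70/30 stratified hold-out
  holdout_auc <- with_seed(seeds[1], {
    test <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      sample(idx, max(1, round(0.3 * length(idx))))
    }))
    train <- setdiff(seq_len(n), test)
    if (length(unique(labels[train])) < 2) NA_real_ else {
      auc_quiet(labels[test], refit_prob(train, test, seeds[2]))
    }
  })
  # leave-one-drug-out
  lodo_prob <- vapply(seq_len(n), function(i) {
    refit_prob(setdiff(seq_len(n), i), i, seeds[3])
  }, numeric(1))
  lodo_auc <- auc_quiet(labels, lodo_prob)
  oob_error <- attr(attr(mvi, "rf"), "oob_error")
  # bootstrap percentile intervals of predicted probabilities
  boot <- matrix(NA_real_, nrow = B, ncol = n)
  imp <- NULL
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[4 + b], sample.int(n, replace = TRUE))
    if (length(unique(labels[idx])) < 2) next
    sub <- fit_rf_high_burden(features[idx, ], labels[idx],
                              seed = seeds[4 + b], n_trees = n_trees,
                              exclude = exclude)
    fit_b <- attr(sub, "model")
    x <- median_impute(features[setdiff(names(features), c("drug", exclude))])
    boot[b, ] <- predict(fit_b, data = as.data.frame(x))$predictions[, "TRUE"]
    if (b <= 100) {
      fit_imp <- ranger::ranger(
        dependent.variable.name = ".y",
        data = data.frame(.y = factor(labels[idx], levels = c(FALSE, TRUE)),
                          median_impute(features[idx, setdiff(names(features),
                                                              c("drug", exclude))]),
                          check.names = FALSE),
        probability = TRUE, num.trees = n_trees, seed = seeds[4 + b],
        importance = "impurity")
      imp <- rbind(imp, ranger::importance(fit_imp))
    }
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  widths <- ci[2, ] - ci[1, ]
  bootstrap <- list(
    per_drug = tibble::tibble(drug = features$drug, lo = ci[1, ], hi = ci[2, ],
                              width = widths),
    median_width = median(widths), iqr_width = stats::IQR(widths),
    range_width = range(widths), B = B
  )
  importance_cv <- apply(imp, 2, function(v) sd(v) / mean(v))
  # weight-specification rank stability
  alt <- composite_raw(mvi$rf_prob, mvi$z_poly, mvi$z_net, mvi$z_sev,
                       weights = alt_weights)
  weight_rank_stability <- list(
    spearman = cor(mvi_percentile(mvi$composite_raw), mvi_percentile(alt),
                   method = "spearman"),
    kendall = cor(mvi_percentile(mvi$composite_raw), mvi_percentile(alt),
                  method = "kendall")
  )
  vif <- vif_components(mvi[c("rf_prob", "z_poly", "z_net", "z_sev")])
  list(holdout_auc = holdout_auc, lodo_auc = lodo_auc, oob_error = oob_error,
       bootstrap = bootstrap, importance_cv = importance_cv,
       weight_rank_stability = weight_rank_stability, vif = vif)
}

#' Derive observed regimens from the cohort
#'
#' Unique suspect-drug sets with at least `min_size` members, with their
#' report counts.
#' @param cases Case-level tibble.
#' @param min_size Minimum regimen size (default 2).
#' @param sep Intra-cell separator.
#' @return Tibble `regimen` (";"-joined sorted drug set), `n_reports`.
#' @export
derive_regimens <- function(cases, min_size = 2, sep = ";") {
  sets <- vapply(cases$suspect_actives,
                 function(s) join_cell(split_cell(s, sep), sep), character(1),
                 USE.NAMES = FALSE)
  sizes <- vapply(sets, function(s) length(split_cell(s, sep)), integer(1),
                  USE.NAMES = FALSE)
  keep <- sizes >= min_size
  counts <- table(sets[keep])
  tibble::tibble(regimen = names(counts), n_reports = as.integer(counts))
}

#' Regimen-level DDI prioritisation score
#'
#' For each regimen (a set of >= 2 drugs): the mechanistic overlap score
#' MOS = fraction of liability axes flagged in at least two regimen members;
#' the network amplification score NAS = percent rank (within the regimen
#' universe) of the summed member degree; the safety vulnerability score
#' SVS = mean member `mvi_pct / 100`; and `DPS = (MOS + NAS + SVS) / 3`,
#' stratified into tiers. Tiering uses absolute thresholds by default
#' (`>= 0.75` high, `>= 0.50` moderate) or, in percentile mode, quantiles of
#' the DPS distribution.
#'
#' @param regimens Tibble from [derive_regimens()] (or with a `regimen`
#'   column of ";"-joined drug sets).
#' @param admet ADMET table carrying the `flag_*` liability axes.
#' @param centrality Node centrality tibble from [node_centrality()].
#' @param mvi MVI table from [mvi_table()].
#' @param tier_mode `"absolute"` or `"percentile"`.
#' @param thresholds Absolute tier thresholds `c(high =, moderate =)`.
#' @param percentile_thresholds Percentile tier thresholds (quantiles of the
#'   DPS distribution) used in percentile mode.
#' @param sep Intra-cell separator.
#' @return Tibble `regimen`, `n_drugs`, `mos`, `nas`, `svs`, `dps`, `tier`.
#' @export
dps_table <- function(regimens, admet, centrality, mvi,
                      tier_mode = c("absolute", "percentile"),
                      thresholds = c(high = 0.75, moderate = 0.50),
                      percentile_thresholds = c(high = 0.90, moderate = 0.75),
                      sep = ";") {
  tier_mode <- rlang::arg_match(tier_mode)
  axes <- intersect(ADMET_FLAGS, names(admet))
  if (!length(axes)) abort("ADMET table carries no liability flag columns.")
  members <- lapply(regimens$regimen, split_cell, sep = sep)
  if (any(lengths(members) < 2)) abort("Every regimen must have at least 2 drugs.")
  mos <- vapply(members, function(m) {
    rows <- admet[match(m, admet$drug), axes, drop = FALSE]
    shared <- vapply(rows, function(col) sum(col, na.rm = TRUE) >= 2, logical(1))
    mean(shared)
  }, numeric(1))
  deg_sum <- vapply(members, function(m) {
    sum(centrality$degree[match(m, centrality$drug)], na.rm = TRUE)
  }, numeric(1))
  nas <- percent_rank01(deg_sum)
  svs <- vapply(members, function(m) {
    mean(mvi$mvi_pct[match(m, mvi$drug)] / 100, na.rm = TRUE)
  }, numeric(1))
  dps <- (mos + nas + svs) / 3
  cut_high <- if (tier_mode == "absolute") thresholds[["high"]] else {
    quantile(dps, percentile_thresholds[["high"]], names = FALSE)
  }
  cut_mod <- if (tier_mode == "absolute") thresholds[["moderate"]] else {
    quantile(dps, percentile_thresholds[["moderate"]], names = FALSE)
  }
  tier <- ifelse(dps >= cut_high, "1-high",
                 ifelse(dps >= cut_mod, "2-moderate", "3-low"))
  tibble::tibble(regimen = regimens$regimen, n_drugs = lengths(members),
                 mos = mos, nas = nas, svs = svs, dps = dps, tier = tier)
}
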