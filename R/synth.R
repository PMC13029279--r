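# Synthetic ICSR cohort generator with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: a deduplicated pregnancy ICSR cohort with heavy polypharmacy
# (median 11 actives per report), a per-active log-odds effect on regulatory
# seriousness, a hub-dominated co-prescription structure, phenotype-linked
# shifts in drug-level ADMET predictors, and literature-style pregnancy PK
# bounds with molecular weights and micromolar potency values.

# Default per-raw-cluster mean shifts (in feature-SD units) for the
# continuous ADMET predictors.  Signs mirror the qualitative contrasts the
# analyses are designed to detect: one cluster with elevated composite risk
# and depressed clearance, one with the reverse, one transporter-flavoured
# cluster with low BSEP IC50 (strong inhibition), and a small cluster with
# high brain penetration.
default_admet_shifts <- function() {
  clusters <- c("C1", "C2", "C3", "C5", "C4")
  m <- matrix(0, nrow = length(clusters), ncol = length(ADMET_CONTINUOUS),
              dimnames = list(clusters, ADMET_CONTINUOUS))
  m["C1", c("ADMET_Risk", "TOX_Risk")] <- 0.8
  m["C1", c("CYP_HLM_CLint", "hERG_pIC50")] <- -0.8
  m["C2", c("ADMET_Risk", "TOX_Risk")] <- -1.0
  m["C2", c("CYP_HLM_CLint", "hERG_pIC50")] <- 1.0
  m["C3", "BSEP_IC50"] <- -1.2
  m["C3", "ADMET_Risk"] <- 0.5
  m["C5", "hmu_fup"] <- 1.0
  m["C4", c("LogBB", "BSEP_IC50")] <- 1.5
  m
}

#' Configuration for the synthetic ICSR cohort generator
#'
#' Bundles and validates every tunable of the generator. The defaults
#' reproduce the study conditions the pipeline is designed for: a
#' polypharmacy distribution with median 11 actives per report, seriousness
#' odds increasing by 5% per additional active, one dominant raw phenotype
#' cluster plus at least one cluster below the 2% harmonisation threshold,
#' and a concentrated hub structure in the co-medication network.
#'
#' @param n_cases Number of deduplicated cases to generate.
#' @param n_drugs Number of antiviral (suspect-eligible) drugs in the catalog.
#' @param n_comed Number of non-antiviral concomitant-only drugs.
#' @param class_mix Named probabilities over drug classes
#'   (INSTI, PI, NNRTI, NRTI, RdRp, other).
#' @param phenotype_probs Named probabilities over raw cluster labels; must
#'   contain at least one label below `0.02` so harmonisation is exercised.
#' @param seriousness_intercept Log-odds intercept of the seriousness model.
#' @param per_active_log_or Log-odds increment per additional active drug
#'   (default `log(1.05)`).
#' @param poly_size,poly_mu Size and mean of the shifted negative binomial
#'   for the number of actives per report (`1 + NB(size, mu)`); defaults are
#'   calibrated so the count distribution has median 11.
#' @param hub_strength Sampling-weight multiplier for backbone hub drugs in
#'   the co-prescription draw (preferential attachment strength).
#' @param n_hubs Number of backbone hub drugs.
#' @param booster_prob Probability that a report includes a pharmacokinetic
#'   booster (ritonavir or cobicistat).
#' @param phenotype_coupling Strength (0-1) of the drug-phenotype linkage:
#'   suspect drugs whose catalog home cluster matches the case's raw cluster
#'   get their sampling weight multiplied by the odds
#'   `coupling / (1 - coupling)`. Raw cluster labels themselves are always
#'   drawn from `phenotype_probs`, so the configured label distribution is
#'   the case-label distribution.
#' @param p_female,p_follow_up,p_literature Marginal probabilities of the
#'   demographic/provenance flags.
#' @param admet_shift_matrix Raw-cluster-by-feature matrix of mean shifts (in
#'   feature SD units) applied to continuous ADMET predictors; defaults to
#'   [default_admet_shifts()].
#' @param admet_missing_frac Fraction of continuous ADMET cells set missing.
#' @param admet_noise_sd Residual SD (in feature SD units) of ADMET values.
#' @param mean_reactions Mean of the Poisson part of the per-case reaction
#'   count (`1 + Poisson(mean_reactions)`).
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_cases,
                         n_drugs = 25,
                         n_comed = 75,
                         class_mix = c(INSTI = 0.20, PI = 0.20, NNRTI = 0.15,
                                       NRTI = 0.30, RdRp = 0.10, other = 0.05),
                         phenotype_probs = c(C1 = 0.55, C3 = 0.24, C2 = 0.13,
                                             C5 = 0.06, C4 = 0.012, C6 = 0.008),
                         seriousness_intercept = 0.50,
                         per_active_log_or = log(1.05),
                         poly_size = 0.60,
                         poly_mu = 19.25,
                         hub_strength = 8,
                         n_hubs = 6,
                         booster_prob = 0.236,
                         phenotype_coupling = 0.9,
                         p_female = 0.90,
                         p_follow_up = 0.40,
                         p_literature = 0.25,
                         admet_shift_matrix = NULL,
                         admet_missing_frac = 0.12,
                         admet_noise_sd = 1,
                         mean_reactions = 3.5,
                         seed = 1L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 0) {
    abort("`n_cases` must be a single non-negative number.")
  }
  if (n_drugs < 1) abort("`n_drugs` must be >= 1.")
  check_prob_vector(class_mix, "class_mix")
  check_prob_vector(phenotype_probs, "phenotype_probs")
  if (!any(phenotype_probs < 0.02)) {
    abort("`phenotype_probs` must include at least one cluster below 0.02 so harmonisation is exercised.")
  }
  stopifnot(poly_size > 0, poly_mu > 0, hub_strength >= 1,
            booster_prob >= 0, booster_prob <= 1,
            phenotype_coupling >= 0, phenotype_coupling <= 1,
            admet_missing_frac >= 0, admet_missing_frac < 1,
            admet_noise_sd >= 0)
  shifts <- admet_shift_matrix %||% default_admet_shifts()
  if (!all(colnames(shifts) %in% ADMET_CONTINUOUS)) {
    bad <- setdiff(colnames(shifts), ADMET_CONTINUOUS)
    abort(paste0("Unknown ADMET feature(s) in shift matrix: ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
         n_comed = as.integer(n_comed), class_mix = class_mix,
         phenotype_probs = phenotype_probs,
         seriousness_intercept = seriousness_intercept,
         per_active_log_or = per_active_log_or,
         poly_size = poly_size, poly_mu = poly_mu,
         hub_strength = hub_strength, n_hubs = as.integer(n_hubs),
         booster_prob = booster_prob,
         phenotype_coupling = phenotype_coupling,
         p_female = p_female, p_follow_up = p_follow_up,
         p_literature = p_literature,
         admet_shift_matrix = shifts,
         admet_missing_frac = admet_missing_frac,
         admet_noise_sd = admet_noise_sd,
         mean_reactions = mean_reactions,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Reaction term vocabulary per raw cluster.  Cluster C3 carries the
# hepatobiliary terms so the reaction-class concordance analysis has signal
# to work with; a shared pool is mixed into every cluster.
reaction_vocabulary <- function() {
  shared <- c("nausea", "vomiting", "headache", "pyrexia", "rash",
              "premature delivery", "abortion spontaneous", "anaemia",
              "drug exposure during pregnancy", "foetal growth restriction")
  list(
    C1 = c(shared, "congenital anomaly", "stillbirth", "neonatal disorder"),
    C2 = c(shared, "dizziness", "insomnia", "depression"),
    C3 = c(shared, "cholestasis", "blood bilirubin increased",
           "alanine aminotransferase increased", "hepatotoxicity"),
    C4 = c(shared, "somnolence", "tremor"),
    C5 = c(shared, "renal impairment", "proteinuria"),
    C6 = c(shared, "urticaria", "pruritus")
  )
}

#' Default hepatobiliary reaction term set
#'
#' Configurable list of reaction terms treated as hepatobiliary for the
#' reaction-class concordance odds ratio.
#' @return Character vector of reaction terms.
#' @export
hepatobiliary_terms <- function() {
  c("cholestasis", "blood bilirubin increased",
    "alanine aminotransferase increased", "aspartate aminotransferase increased",
    "hepatotoxicity", "liver function test abnormal", "jaundice")
}

# Build the drug catalog: antivirals (suspect-eligible) + concomitant-only
# drugs + the two boosters. Hub weights implement preferential attachment
# over a fixed backbone set.
build_catalog <- function(config) {
  seeds <- derive_seeds(config$seed, 4, salt = 101L)
  antivirals <- sprintf("av%02d", seq_len(config$n_drugs))
  comeds <- if (config$n_comed > 0) sprintf("comed%02d", seq_len(config$n_comed)) else character(0)
  boosters <- c("ritonavir", "cobicistat")
  with_seed(seeds[1], {
    classes <- sample(names(config$class_mix), config$n_drugs,
                      replace = TRUE, prob = config$class_mix)
    home <- sample(names(config$phenotype_probs),
                   config$n_drugs + config$n_comed + 2L,
                   replace = TRUE, prob = config$phenotype_probs)
    popularity <- exp(rnorm(config$n_drugs, 0, 0.8))
    mw <- round(runif(config$n_drugs + config$n_comed + 2L, 200, 800), 1)
    drug <- c(antivirals, comeds, boosters)
    n_total <- length(drug)
    hub_idx <- sample.int(n_total, min(config$n_hubs, n_total))
    hub_weight <- rep(1, n_total)
    hub_weight[hub_idx] <- config$hub_strength
    tibble::tibble(
      drug = drug,
      drug_class = c(classes, rep("other", config$n_comed), "other", "other"),
      suspect_eligible = c(rep(TRUE, config$n_drugs),
                           rep(FALSE, config$n_comed), FALSE, FALSE),
      is_booster = drug %in% boosters,
      home_cluster = home,
      popularity = c(popularity, rep(NA_real_, config$n_comed + 2L)),
      hub_weight = hub_weight,
      mw = mw
    )
  })
}

#' Generate a synthetic ICSR cohort with ground truth
#'
#' Draws a deduplicated case-level cohort: per-case suspect and concomitant
#' active sets (hub-weighted sampling without replacement), a raw phenotype
#' cluster label coupled to the primary suspect's home cluster, reaction
#' terms from a cluster-specific vocabulary, and a regulatory seriousness
#' flag drawn from `Bernoulli(plogis(intercept + log_or * poly_actives))`.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `cases` (tibble, one row per case),
#'   `catalog` (drug catalog tibble) and `ground_truth` (list of the
#'   parameters a recovery analysis should reproduce).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  catalog <- build_catalog(config)
  vocab <- reaction_vocabulary()
  gt <- list(
    true_per_active_or = exp(config$per_active_log_or),
    seriousness_intercept = config$seriousness_intercept,
    true_admet_shifts = config$admet_shift_matrix,
    hub_drugs = catalog$drug[catalog$hub_weight > 1],
    phenotype_probs = config$phenotype_probs,
    booster_prob = config$booster_prob
  )
  if (config$n_cases == 0) {
    cases <- tibble::tibble(
      case_id = character(0), suspect_actives = character(0),
      concomitant_actives = character(0), reactions = character(0),
      serious = logical(0), sex = character(0), follow_up = logical(0),
      literature = logical(0), raw_cluster = character(0)
    )
    return(list(cases = cases, catalog = catalog, ground_truth = gt))
  }

  n <- config$n_cases
  av <- catalog[catalog$suspect_eligible, ]
  pool <- catalog[!catalog$suspect_eligible & !catalog$is_booster, ]
  boosters <- catalog$drug[catalog$is_booster]
  seeds <- derive_seeds(config$seed, 1, salt = 202L)

  with_seed(seeds[1], {
    n_suspect <- pmin(1L + rbinom(n, 2L, 0.45), nrow(av))
    n_react <- 1L + rpois(n, config$mean_reactions)
    n_total_target <- 1L + rnbinom(n, size = config$poly_size, mu = config$poly_mu)
    has_booster <- runif(n) < config$booster_prob
    # raw cluster drawn from phenotype_probs directly, so the configured
    # label distribution is the case-label distribution; the drug-phenotype
    # linkage is induced below by biasing suspect selection toward drugs
    # whose home cluster matches the case's cluster
    raw_cluster <- sample(names(config$phenotype_probs), n, replace = TRUE,
                          prob = config$phenotype_probs)
    couple_odds <- config$phenotype_coupling / max(1e-9, 1 - config$phenotype_coupling)
    sex <- ifelse(runif(n) < config$p_female, "F", "M")
    follow_up <- runif(n) < config$p_follow_up
    literature <- runif(n) < config$p_literature

    suspects <- vector("list", n)
    concoms <- vector("list", n)
    reactions <- character(n)
    n_pool_max <- nrow(pool)
    for (i in seq_len(n)) {
      w <- av$popularity * ifelse(av$home_cluster == raw_cluster[i],
                                  couple_odds, 1)
      sus <- sample(av$drug, n_suspect[i], prob = w)
      # concomitant draw: hub-weighted, without replacement, from the
      # concomitant pool; booster appended when drawn
      extra <- if (has_booster[i]) sample(boosters, 1L) else character(0)
      n_con <- max(0L, min(n_total_target[i], n_suspect[i] + n_pool_max +
                             length(extra)) - n_suspect[i] - length(extra))
      con <- if (n_con > 0) {
        sample(pool$drug, n_con, prob = pool$hub_weight)
      } else character(0)
      con <- c(con, extra)
      suspects[[i]] <- sort(sus)
      concoms[[i]] <- sort(con)
      terms <- vocab[[raw_cluster[i]]] %||% vocab[["C1"]]
      reactions[i] <- join_cell(sample(terms, min(n_react[i], length(terms))))
    }
    poly_total <- lengths(suspects) + lengths(concoms)
    serious <- runif(n) < plogis(config$seriousness_intercept +
                                   config$per_active_log_or * poly_total)
    cases <- tibble::tibble(
      case_id = sprintf("EU-%06d", seq_len(n)),
      suspect_actives = vapply(suspects, join_cell, character(1)),
      concomitant_actives = vapply(concoms, join_cell, character(1)),
      reactions = reactions,
      serious = serious,
      sex = sex,
      follow_up = follow_up,
      literature = literature,
      raw_cluster = raw_cluster
    )
    list(cases = cases, catalog = catalog, ground_truth = gt)
  })
}

#' Generate a drug-level ADMET feature table
#'
#' Continuous features are drawn as `global mean + shift * feature SD +
#' noise`, where the shift is looked up from the drug's home cluster in the
#' shift matrix. A configurable fraction of continuous cells is set missing
#' (to exercise median imputation downstream); binary liability flags are
#' drawn per drug.
#'
#' @param catalog Drug catalog tibble (from [generate_cohort()]), or any
#'   tibble with `drug` and `home_cluster` columns.
#' @param shifts Cluster-by-feature shift matrix in feature-SD units
#'   (default [default_admet_shifts()]).
#' @param missing_frac Fraction of continuous cells set to `NA`.
#' @param noise_sd Residual SD in feature-SD units (0 gives noiseless values).
#' @param flag_prob Bernoulli probability for each liability flag.
#' @param seed Integer seed.
#' @return Tibble with one row per drug: continuous ADMET columns plus
#'   `flag_*` liability columns.
#' @export
generate_admet_table <- function(catalog, shifts = default_admet_shifts(),
                                 missing_frac = 0.12, noise_sd = 1,
                                 flag_prob = 0.3, seed = 1L) {
  if (!all(colnames(shifts) %in% ADMET_CONTINUOUS)) {
    bad <- setdiff(colnames(shifts), ADMET_CONTINUOUS)
    abort(paste0("Unknown ADMET feature(s) in shift matrix: ",
                 paste(bad, collapse = ", ")))
  }
  # global location/scale per feature (units: score, score, uL/min/mg, uM,
  # -log10(M), log ratio, fraction)
  base_mean <- c(ADMET_Risk = 5, TOX_Risk = 2, CYP_HLM_CLint = 30,
                 BSEP_IC50 = 60, hERG_pIC50 = 5, LogBB = -0.5, hmu_fup = 0.15)
  base_sd <- c(ADMET_Risk = 1, TOX_Risk = 0.8, CYP_HLM_CLint = 12,
               BSEP_IC50 = 25, hERG_pIC50 = 0.8, LogBB = 0.6, hmu_fup = 0.08)
  n <- nrow(catalog)
  with_seed(seed, {
    out <- tibble::tibble(drug = catalog$drug)
    for (f in ADMET_CONTINUOUS) {
      shift <- rep(0, n)
      if (f %in% colnames(shifts)) {
        idx <- match(catalog$home_cluster, rownames(shifts))
        shift <- ifelse(is.na(idx), 0, shifts[cbind(idx, match(f, colnames(shifts)))])
      }
      out[[f]] <- base_mean[[f]] + shift * base_sd[[f]] +
        rnorm(n, 0, noise_sd * base_sd[[f]])
    }
    if (missing_frac > 0) {
      cells <- as.matrix(out[ADMET_CONTINUOUS])
      miss <- matrix(runif(length(cells)) < missing_frac, nrow = n)
      cells[miss] <- NA_real_
      for (j in seq_along(ADMET_CONTINUOUS)) out[[ADMET_CONTINUOUS[j]]] <- cells[, j]
    }
    for (f in ADMET_FLAGS) out[[f]] <- runif(n) < flag_prob
    out
  })
}

#' Generate pregnancy PK bounds and potency tables
#'
#' Emulates literature-curated, stage-specific exposure bounds: for each drug
#' and pregnancy stage, Cmax (ug/mL) and AUC0-24 (ug*h/mL) minimum/maximum/
#' central values, with molecular weight attached; plus a potency table of
#' micromolar IC50/Ki values per drug and mechanism.
#'
#' @param catalog Drug catalog tibble with `drug` and `mw` columns.
#' @param drugs Drugs to cover (default: first 15 suspect-eligible drugs).
#' @param stages Pregnancy stages to cover.
#' @param pk_spec Optional tibble overriding the random generation: columns
#'   `drug`, `stage`, `metric`, `min`, `max`, `central` (either bounds with
#'   `min <= max`, or a single central value). Molecular weight is still
#'   attached from the catalog.
#' @param mechanisms Potency mechanisms to generate.
#' @param seed Integer seed.
#' @return List with `pk_bounds` and `potency` tibbles.
#' @export
generate_pk_tables <- function(catalog,
                               drugs = NULL,
                               stages = c("trimester2", "trimester3", "postpartum"),
                               pk_spec = NULL,
                               mechanisms = c("BSEP_IC50", "CYP1A2_Ki",
                                              "CYP2D6_Ki", "CYP3A4_Ki"),
                               seed = 1L) {
  if (any(catalog$mw <= 0, na.rm = TRUE)) abort("Molecular weights must be positive.")
  if (is.null(drugs)) {
    elig <- if ("suspect_eligible" %in% names(catalog)) {
      catalog$drug[catalog$suspect_eligible]
    } else {
      catalog$drug
    }
    drugs <- head(elig, 15)
  }
  if (length(drugs) == 0) {
    return(list(
      pk_bounds = tibble::tibble(drug = character(0), stage = character(0),
                                 metric = character(0), min = numeric(0),
                                 max = numeric(0), central = numeric(0),
                                 unit = character(0), mw = numeric(0)),
      potency = tibble::tibble(drug = character(0), mechanism = character(0),
                               value_uM = numeric(0))
    ))
  }
  if (!is.null(pk_spec)) {
    bad <- !is.na(pk_spec$min) & !is.na(pk_spec$max) & pk_spec$min > pk_spec$max
    if (any(bad)) abort("PK spec has rows with min > max.")
    pk <- pk_spec
    pk$unit <- ifelse(pk$metric == "Cmax", "ug/mL", "ug*h/mL")
    pk$mw <- catalog$mw[match(pk$drug, catalog$drug)]
    if (any(is.na(pk$mw))) abort("PK spec names drugs absent from the catalog.")
  } else {
    grid <- tidyr::expand_grid(drug = drugs, stage = stages,
                               metric = c("Cmax", "AUC0_24"))
    pk <- with_seed(seed, {
      central <- exp(rnorm(nrow(grid), ifelse(grid$metric == "Cmax",
                                              log(2), log(30)), 0.6))
      lo <- central * runif(nrow(grid), 0.5, 0.9)
      hi <- central * runif(nrow(grid), 1.1, 2.0)
      # a minority of rows carry only a central estimate (no bounds)
      central_only <- runif(nrow(grid)) < 0.2
      tibble::tibble(
        drug = grid$drug, stage = grid$stage, metric = grid$metric,
        min = ifelse(central_only, NA_real_, lo),
        max = ifelse(central_only, NA_real_, hi),
        central = central,
        unit = ifelse(grid$metric == "Cmax", "ug/mL", "ug*h/mL"),
        mw = catalog$mw[match(grid$drug, catalog$drug)]
      )
    })
  }
  potency <- with_seed(seed + 1L, {
    grid <- tidyr::expand_grid(drug = drugs, mechanism = mechanisms)
    tibble::tibble(drug = grid$drug, mechanism = grid$mechanism,
                   value_uM = exp(rnorm(nrow(grid), log(20), 1)))
  })
  list(pk_bounds = pk, potency = potency)
}

#' Write the synthetic input tables to delimited text
#'
#' Writes the case-level table, ADMET table, PK bounds and potency tables as
#' comma-separated UTF-8 text with header rows, plus the ground-truth record
#' as JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param admet Result of [generate_admet_table()].
#' @param pk Result of [generate_pk_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_inputs <- function(cohort, admet, pk, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cases = file.path(dir, "cases.csv"),
    catalog = file.path(dir, "catalog.csv"),
    admet = file.path(dir, "admet.csv"),
    pk_bounds = file.path(dir, "pk_bounds.csv"),
    potency = file.path(dir, "potency.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(cohort$cases, paths[["cases"]])
  readr::write_csv(cohort$catalog, paths[["catalog"]])
  readr::write_csv(admet, paths[["admet"]])
  readr::write_csv(pk$pk_bounds, paths[["pk_bounds"]])
  readr::write_csv(pk$potency, paths[["potency"]])
  gt <- cohort$ground_truth
  gt$true_admet_shifts <- as.data.frame(gt$true_admet_shifts)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
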