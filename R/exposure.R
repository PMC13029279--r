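# Range-based Monte Carlo exposure-potency ratio engine: unit conversion,
# uniform sampling within literature pregnancy PK bounds, and exceedance
# probabilities against micromolar potency thresholds.

#' Convert a mass concentration to micromolar
#'
#' `uM = (ug/mL) * 1000 / MW`.
#' @param c_ugml Concentration in ug/mL (or ug*h/mL for AUC-derived values).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Concentration in uM.
#' @export
to_micromolar <- function(c_ugml, mw) {
  if (any(mw <= 0)) abort("Molecular weight must be positive.")
  c_ugml * 1000 / mw
}

#' 24-hour average concentration from AUC
#'
#' `Cavg24 = AUC0-24 / 24`.
#' @param auc AUC over 24 h in ug*h/mL (>= 0).
#' @return Average concentration in ug/mL.
#' @export
cavg24 <- function(auc) {
  stopifnot(all(auc >= 0))
  auc / 24
}

#' Analytic exceedance probability of a uniform exposure
#'
#' Closed-form `P(U(a, b) > threshold) = clamp((b - threshold)/(b - a), 0, 1)`;
#' for a degenerate bound (`a == b`) the indicator `a > threshold`. Serves
#' as the independent oracle for the Monte Carlo sampler.
#' @param a,b Lower and upper bound (`a <= b`).
#' @param threshold Exceedance threshold.
#' @return Probability in `[0, 1]`.
#' @export
analytic_exceedance <- function(a, b, threshold) {
  stopifnot(a <= b)
  if (a == b) return(as.numeric(a > threshold))
  min(1, max(0, (b - threshold) / (b - a)))
}

#' Monte Carlo exposure-potency ratio summary for one drug-stage-ratio
#'
#' Samples `n` exposures uniformly within the reported minimum-maximum
#' bounds (degenerate at the central estimate when bounds are absent),
#' converts to micromolar via molecular weight (AUC metrics are first
#' reduced to `Cavg24`), divides by the potency threshold, and summarises
#' the ratio distribution: median, 2.5/97.5 percentiles and the exceedance
#' probabilities `P(ratio > 1)` and `P(ratio > 10)` (strict inequality).
#'
#' @param bound One-row PK bound (list or tibble row) with fields `drug`,
#'   `stage`, `metric` (`"Cmax"` or `"AUC0_24"`), `min`, `max`, `central`,
#'   `mw`.
#' @param potency Potency threshold in uM (> 0).
#' @param ratio_name Label, e.g. `"Cmax/BSEP_IC50"`.
#' @param n Number of Monte Carlo samples (default 10000).
#' @param seed Integer seed.
#' @return One-row tibble: drug, stage, ratio_name, median, lo95, hi95,
#'   p_gt_1, p_gt_10, n_samples, seed.
#' @export
simulate_ratios <- function(bound, potency, ratio_name = NULL, n = 10000,
                            seed = 1L) {
  if (is.na(potency) || potency <= 0) abort("`potency` must be positive.")
  has_bounds <- !is.na(bound$min) && !is.na(bound$max)
  if (!has_bounds && is.na(bound$central)) {
    abort("No exposure information: need (min, max) bounds or a central value.")
  }
  if (has_bounds && bound$min > bound$max) abort("Bound has min > max.")
  exposure <- with_seed(seed, {
    if (has_bounds) runif(n, bound$min, bound$max) else rep(bound$central, n)
  })
  if (identical(bound$metric, "AUC0_24")) exposure <- cavg24(exposure)
  ratio <- to_micromolar(exposure, bound$mw) / potency
  if (is.null(ratio_name)) {
    ratio_name <- paste0(if (identical(bound$metric, "AUC0_24")) "Cavg24" else
      bound$metric, "/potency")
  }
  tibble::tibble(
    drug = bound$drug, stage = bound$stage, ratio_name = ratio_name,
    median = median(ratio),
    lo95 = quantile(ratio, 0.025, names = FALSE),
    hi95 = quantile(ratio, 0.975, names = FALSE),
    p_gt_1 = mean(ratio > 1),
    p_gt_10 = mean(ratio > 10),
    n_samples = n, seed = seed
  )
}

#' Exposure-liability panel over all drug x stage x mechanism combinations
#'
#' Runs [simulate_ratios()] for every PK-bound row crossed with every
#' potency mechanism available for the same drug. Stage rows are never
#' pooled. Ratio names follow the `Cmax/BSEP_IC50`, `Cavg24/CYP1A2_Ki`
#' convention.
#'
#' @param pk_bounds PK bounds tibble (see [generate_pk_tables()]).
#' @param potency Potency tibble with `drug`, `mechanism`, `value_uM`.
#' @param n Samples per combination.
#' @param seed Integer seed; each combination gets its own derived sub-seed.
#' @return Tibble of ratio summaries.
#' @export
exposure_liability_panel <- function(pk_bounds, potency, n = 10000, seed = 1L) {
  combos <- dplyr::inner_join(pk_bounds, potency, by = "drug",
                              relationship = "many-to-many")
  if (!nrow(combos)) return(tibble::tibble())
  seeds <- derive_seeds(seed, nrow(combos), salt = 17L)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    row <- combos[i, ]
    label <- paste0(if (row$metric == "AUC0_24") "Cavg24" else row$metric,
                    "/", row$mechanism)
    simulate_ratios(row, row$value_uM, ratio_name = label, n = n,
                    seed = seeds[i])
  })
  dplyr::bind_rows(rows)
}

#' Path to a user-supplied curated pregnancy PK table
#'
#' The exposure-liability reproduction of published per-drug exceedance
#' values requires the curated supplementary PK-bound and potency tables,
#' which are not distributed with the package. When a curated CSV is placed
#' at `inst/extdata/<name>` (or supplied at this path in an installed
#' library), this helper returns its path; otherwise `NA` with a message.
#' @param name File name searched under the package's `extdata`.
#' @return Path or `NA_character_`.
#' @export
curated_pk_path <- function(name = "pregnancy_pk_curated.csv") {
  p <- system.file("extdata", name, package = "pregvig")
  if (!nzchar(p)) {
    inform(paste0("Curated pregnancy PK table '", name, "' not available; ",
                  "published per-drug exceedance values cannot be recomputed ",
                  "without it."))
    return(NA_character_)
  }
  p
}
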