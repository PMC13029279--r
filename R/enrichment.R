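# Drug-phenotype contextual disproportionality: 2x2 tables under primary or
# all-suspect attribution, reporting odds ratios with Fisher exact tests,
# Benjamini-Hochberg FDR, observed/expected enrichment, and the attribution
# sensitivity (Jaccard) analysis.

#' Drug-phenotype 2x2 contingency tables
#'
#' Builds, at the deduplicated case level, one 2x2 table per drug-phenotype
#' pair: `a` = cases attributed to the drug with the phenotype, `b` = drug,
#' other phenotype, `c` = other drug, phenotype, `d` = neither. Under
#' `"primary"` attribution each case counts for exactly one drug (so
#' `a + b + c + d = n_cases` for every pair and the `a` counts partition the
#' cohort); under `"all_suspect"` a case counts for each of its suspect
#' drugs.
#'
#' @param cases Case-level tibble.
#' @param map Phenotype map.
#' @param catalog Drug catalog (needed for primary attribution).
#' @param attribution `"primary"` or `"all_suspect"`.
#' @param sep Intra-cell separator.
#' @return Tibble `drug`, `phenotype`, `a`, `b`, `c`, `d`, `n_cases_drug`.
#' @export
drug_phenotype_tables <- function(cases, map, catalog = NULL,
                                  attribution = c("primary", "all_suspect"),
                                  sep = ";") {
  attribution <- rlang::arg_match(attribution)
  cc <- apply_phenotype_map(cases, map)
  n <- nrow(cc)
  pairs <- if (attribution == "primary") {
    if (is.null(catalog)) abort("Primary attribution requires a drug catalog.")
    tibble::tibble(case_id = cc$case_id,
                   drug = assign_primary_active(cc, catalog, sep = sep),
                   phenotype = cc$phenotype)
  } else {
    cc |>
      dplyr::transmute(case_id = .data$case_id, drug = .data$suspect_actives,
                       phenotype = .data$phenotype) |>
      tidyr::separate_rows("drug", sep = sep)
  }
  drugs <- sort(unique(pairs$drug))
  phenos <- sort(unique(cc$phenotype))
  pheno_n <- table(factor(cc$phenotype, levels = phenos))
  counts <- as.matrix(table(factor(pairs$drug, levels = drugs),
                            factor(pairs$phenotype, levels = phenos)))
  drug_n <- as.numeric(table(factor(pairs$drug, levels = drugs)))
  grid <- tidyr::expand_grid(drug = drugs, phenotype = phenos)
  a <- counts[cbind(match(grid$drug, drugs), match(grid$phenotype, phenos))]
  nd <- drug_n[match(grid$drug, drugs)]
  np <- as.numeric(pheno_n)[match(grid$phenotype, phenos)]
  tibble::tibble(
    drug = grid$drug, phenotype = grid$phenotype,
    a = as.integer(a), b = as.integer(nd - a),
    c = as.integer(np - a), d = as.integer(n - nd - np + a),
    n_cases_drug = as.integer(nd)
  )
}

#' Reporting odds ratio with Fisher exact test for one 2x2 table
#'
#' `ROR = (a d)/(b c)`, with the Haldane-Anscombe 0.5 correction added to
#' all four cells when (and only when) any cell is zero; Woolf log-normal
#' 95% CI; two-sided Fisher exact p.
#'
#' @param a,b,c,d Non-negative cell counts (a = drug & phenotype).
#' @return List `ror`, `ci_lo`, `ci_hi`, `p`, `corrected`.
#' @export
ror_fisher <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("Cell counts must be non-negative.")
  if (all(cells == 0)) abort("All-zero 2x2 table.")
  corrected <- any(cells == 0)
  adj <- if (corrected) cells + 0.5 else cells
  ror <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  se <- sqrt(sum(1 / adj))
  p <- min(1, fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value)
  list(ror = ror,
       ci_lo = ror * exp(-qnorm(0.975) * se),
       ci_hi = ror * exp(qnorm(0.975) * se),
       p = p, corrected = corrected)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement. `NA` p-values are excluded
#' from the correction (and returned as `NA`) with a message.
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  na <- is.na(pvals)
  if (any(na)) inform(sprintf("%d NA p-value(s) excluded from BH correction.", sum(na)))
  out <- rep(NA_real_, length(pvals))
  out[!na] <- p.adjust(pvals[!na], method = "BH")
  out
}

#' Observed/expected enrichment ratio of a 2x2 table
#'
#' Observed `a` divided by its expectation under independence,
#' `(a+b)(a+c)/N`. Undefined (NA, with a message) when a margin is zero.
#' @inheritParams ror_fisher
#' @return Numeric O/E ratio.
#' @export
oe_enrichment <- function(a, b, c, d) {
  n <- a + b + c + d
  expected <- (a + b) * (a + c) / n
  if (!is.finite(expected) || expected == 0) {
    inform("Zero margin: O/E enrichment undefined.")
    return(NA_real_)
  }
  a / expected
}

#' Full drug-phenotype enrichment panel
#'
#' Computes ROR, Fisher p, BH q (across the whole panel), O/E ratio and the
#' enriched flag (`q < fdr & ror > 1`) for every drug-phenotype pair.
#'
#' @inheritParams drug_phenotype_tables
#' @param fdr FDR threshold for the enriched flag (default 0.05).
#' @return Long-format tibble: drug, phenotype, a, b, c, d, ror, ci_lo,
#'   ci_hi, p, q, oe_ratio, enriched.
#' @export
enrichment_panel <- function(cases, map, catalog = NULL,
                             attribution = c("primary", "all_suspect"),
                             fdr = 0.05, sep = ";") {
  tabs <- drug_phenotype_tables(cases, map, catalog, attribution, sep = sep)
  stats <- purrr::pmap(tabs[c("a", "b", "c", "d")], function(a, b, c, d) {
    rf <- ror_fisher(a, b, c, d)
    oe <- suppressMessages(oe_enrichment(a, b, c, d))
    tibble::tibble(ror = rf$ror, ci_lo = rf$ci_lo, ci_hi = rf$ci_hi,
                   p = rf$p, oe_ratio = oe)
  })
  out <- dplyr::bind_cols(tabs, dplyr::bind_rows(stats))
  out$q <- bh_fdr(out$p)
  out$enriched <- !is.na(out$q) & out$q < fdr & out$ror > 1
  out
}

#' Attribution sensitivity: top-k Jaccard overlap per phenotype
#'
#' Compares the primary-attribution and all-suspect-attribution enrichment
#' panels: per phenotype, the Jaccard overlap of the top-`k` drugs ranked by
#' O/E ratio (ties broken by q then drug name). Phenotypes with fewer than
#' `k` drugs use all available drugs (with a message).
#'
#' @param results_primary,results_all_suspect Panels from
#'   [enrichment_panel()] computed on the same cohort.
#' @param k Top-list size (default 10).
#' @return Tibble `phenotype`, `jaccard`, `n_shared`, `n_union`.
#' @export
attribution_sensitivity <- function(results_primary, results_all_suspect, k = 10) {
  top_k <- function(res, ph) {
    sub <- res[res$phenotype == ph & !is.na(res$oe_ratio), ]
    if (nrow(sub) < k) {
      inform(sprintf("Phenotype '%s': only %d drugs available (k = %d).",
                     ph, nrow(sub), k))
    }
    sub <- sub[order(-sub$oe_ratio, sub$q, sub$drug), ]
    head(sub$drug, k)
  }
  phenos <- sort(intersect(unique(results_primary$phenotype),
                           unique(results_all_suspect$phenotype)))
  purrr::map_dfr(phenos, function(ph) {
    t1 <- top_k(results_primary, ph)
    t2 <- top_k(results_all_suspect, ph)
    shared <- length(intersect(t1, t2))
    uni <- length(union(t1, t2))
    tibble::tibble(phenotype = ph, jaccard = shared / uni,
                   n_shared = shared, n_union = uni)
  })
}
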