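# Phenotype harmonisation and phenotype-level summaries: seriousness,
# ADMET signatures, Kruskal-Wallis significance panel, one-way ICC, and
# reaction-class concordance odds ratios.

#' Harmonise raw cluster labels into stable phenotypes
#'
#' Raw cluster labels whose case-level frequency falls below
#' `threshold_frac` are collapsed into a single `"Other"` phenotype; all
#' remaining labels map to themselves.
#'
#' @param cases Case-level tibble with a `raw_cluster` column.
#' @param threshold_frac Collapse threshold as a fraction of cases
#'   (default 0.02).
#' @return A tibble (class `phenotype_map`) with columns `raw`,
#'   `harmonised`, `frequency`.
#' @export
harmonise_phenotypes <- function(cases, threshold_frac = 0.02) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    abort("`threshold_frac` must lie strictly between 0 and 1.")
  }
  if (any(is.na(cases$raw_cluster))) abort("Every case must carry a raw cluster label.")
  freq <- table(cases$raw_cluster) / nrow(cases)
  map <- tibble::tibble(
    raw = names(freq),
    frequency = as.numeric(freq),
    harmonised = ifelse(as.numeric(freq) < threshold_frac, "Other", names(freq))
  )
  structure(map[c("raw", "harmonised", "frequency")],
            threshold_frac = threshold_frac,
            class = c("phenotype_map", class(map)))
}

#' Apply a phenotype map to a table
#'
#' Adds a `phenotype` column by mapping the table's raw cluster labels
#' through the harmonisation map.
#' @param x Tibble with a `raw_cluster` or `cluster` column.
#' @param map A [harmonise_phenotypes()] map.
#' @return `x` with a `phenotype` column appended.
#' @export
apply_phenotype_map <- function(x, map) {
  col <- if ("raw_cluster" %in% names(x)) "raw_cluster" else "cluster"
  if (!col %in% names(x)) abort("`x` must have a `raw_cluster` or `cluster` column.")
  idx <- match(x[[col]], map$raw)
  if (any(is.na(idx))) {
    abort(paste0("Raw label(s) not covered by the phenotype map: ",
                 paste(unique(x[[col]][is.na(idx)]), collapse = ", ")))
  }
  x$phenotype <- map$harmonised[idx]
  x
}

#' Seriousness by harmonised phenotype
#'
#' Case-level serious fractions per phenotype, with a stability flag for
#' phenotypes below a configurable case-count floor.
#'
#' @param cases Case-level tibble.
#' @param map Phenotype map.
#' @param min_cases Stability floor (default 5).
#' @return Tibble `phenotype`, `n_cases`, `serious_frac`, `stability_flag`
#'   (`TRUE` when the estimate rests on at least `min_cases` cases).
#' @export
seriousness_by_phenotype <- function(cases, map, min_cases = 5) {
  apply_phenotype_map(cases, map) |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(n_cases = dplyr::n(),
                     serious_frac = mean(.data$serious), .groups = "drop") |>
    dplyr::mutate(stability_flag = .data$n_cases >= min_cases)
}

#' Phenotype-level ADMET signature matrix
#'
#' For each phenotype and continuous ADMET feature: the median of the
#' feature over expanded records (each record carrying its drug's value),
#' z-scored across phenotypes within feature (sample, n-1, scaling, under
#' which a single extreme phenotype among five can reach at most
#' z = 4/sqrt(5) = 1.79). Features with no observed values are excluded
#' with a message;
#' features whose phenotype medians are all identical get z = 0 and are
#' listed in the `constant_features` attribute.
#'
#' @param expanded Expanded record tibble (from [expand_cases()]).
#' @param admet ADMET table with one row per drug.
#' @param map Phenotype map.
#' @param features Continuous features to profile.
#' @return A phenotype-by-feature matrix of z-scored medians with attributes
#'   `medians` (raw medians) and `constant_features`.
#' @export
admet_signature <- function(expanded, admet, map,
                            features = intersect(ADMET_CONTINUOUS, names(admet))) {
  recs <- apply_phenotype_map(expanded, map)
  recs <- dplyr::left_join(recs, admet[c("drug", features)], by = "drug")
  phenos <- sort(unique(recs$phenotype))
  med <- matrix(NA_real_, nrow = length(phenos), ncol = length(features),
                dimnames = list(phenos, features))
  for (f in features) {
    vals <- tapply(recs[[f]], recs$phenotype, median, na.rm = TRUE)
    med[names(vals), f] <- vals
  }
  all_missing <- colSums(!is.na(med)) == 0
  if (any(all_missing)) {
    inform(paste0("Feature(s) with no observed values excluded: ",
                  paste(features[all_missing], collapse = ", ")))
    med <- med[, !all_missing, drop = FALSE]
  }
  z <- med
  constant <- character(0)
  for (j in seq_len(ncol(med))) {
    col <- med[, j]
    ok <- !is.na(col)
    if (length(unique(col[ok])) < 2) {
      z[ok, j] <- 0
      constant <- c(constant, colnames(med)[j])
    } else {
      z[ok, j] <- zscore(col[ok])
    }
  }
  structure(z, medians = med, constant_features = constant)
}

#' Tidy long-format view of a signature matrix
#' @param sig Matrix from [admet_signature()].
#' @return Tibble `phenotype`, `feature`, `z`.
#' @export
signature_tidy <- function(sig) {
  tibble::tibble(
    phenotype = rep(rownames(sig), times = ncol(sig)),
    feature = rep(colnames(sig), each = nrow(sig)),
    z = as.vector(sig)
  )
}

#' Kruskal-Wallis panel across phenotypes
#'
#' Tests each continuous feature for global differences across phenotypes at
#' the expanded-record level (tie-corrected Kruskal-Wallis H), with
#' Benjamini-Hochberg correction across the feature panel. Features
#' represented in fewer than two phenotypes are skipped with a message.
#'
#' @inheritParams admet_signature
#' @return Tibble `feature`, `H`, `df`, `p`, `q`.
#' @export
kw_panel <- function(expanded, admet, map,
                     features = intersect(ADMET_CONTINUOUS, names(admet))) {
  recs <- apply_phenotype_map(expanded, map)
  recs <- dplyr::left_join(recs, admet[c("drug", features)], by = "drug")
  rows <- lapply(features, function(f) {
    ok <- !is.na(recs[[f]])
    groups <- factor(recs$phenotype[ok])
    if (nlevels(droplevels(groups)) < 2) {
      inform(sprintf("Feature '%s' represented in <2 phenotypes; skipped.", f))
      return(NULL)
    }
    kt <- kruskal.test(recs[[f]][ok], droplevels(groups))
    tibble::tibble(feature = f, H = unname(kt$statistic),
                   df = unname(kt$parameter), p = kt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' `ICC(1) = (MSB - MSW) / (MSB + (k0 - 1) MSW)` with the unbalanced-design
#' group-size constant `k0 = (N - sum(n_i^2)/N) / (k - 1)`, truncated at 0
#' from below. When all observations are identical the ICC is defined as 0
#' with `degenerate = TRUE`.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length.
#' @return List with `icc`, `msb`, `msw`, `k0`, `n_groups`, `degenerate`.
#' @export
icc_one_way <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) abort("ICC requires at least 2 groups.")
  if (n - k < 1) abort("ICC requires more observations than groups.")
  if (length(unique(values)) == 1) {
    return(list(icc = 0, msb = 0, msw = 0, k0 = NA_real_,
                n_groups = k, degenerate = TRUE))
  }
  ni <- as.numeric(table(groups))
  grand <- mean(values)
  gmeans <- tapply(values, groups, mean)
  ssb <- sum(ni * (gmeans - grand)^2)
  ssw <- sum((values - gmeans[groups])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  k0 <- (n - sum(ni^2) / n) / (k - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  list(icc = max(0, icc), msb = msb, msw = msw, k0 = k0,
       n_groups = k, degenerate = FALSE)
}

#' Reaction-class concordance odds ratio for one phenotype
#'
#' Case-level 2x2 odds ratio of reaction-term-set membership (any reaction
#' in `term_set`) in the given phenotype versus all other phenotypes, with
#' Woolf log-normal 95% CI and Haldane-Anscombe 0.5 correction applied to
#' all cells when any cell is zero.
#'
#' @param cases Case-level tibble.
#' @param map Phenotype map.
#' @param term_set Non-empty character vector of reaction terms.
#' @param phenotype Phenotype of interest.
#' @param sep Intra-cell separator for the reactions column.
#' @return List `or`, `ci_lo`, `ci_hi`, `table` (a,b,c,d), `corrected`.
#' @export
reaction_class_or <- function(cases, map, term_set, phenotype, sep = ";") {
  if (!length(term_set)) abort("`term_set` must be non-empty.")
  cc <- apply_phenotype_map(cases, map)
  in_ph <- cc$phenotype == phenotype
  if (!any(in_ph)) abort(sprintf("Phenotype '%s' has no cases.", phenotype))
  has_term <- vapply(cc$reactions, function(r) any(split_cell(r, sep) %in% term_set),
                     logical(1), USE.NAMES = FALSE)
  a <- sum(in_ph & has_term)
  b <- sum(in_ph & !has_term)
  c_ <- sum(!in_ph & has_term)
  d <- sum(!in_ph & !has_term)
  cells <- c(a = a, b = b, c = c_, d = d)
  corrected <- any(cells == 0)
  adj <- if (corrected) cells + 0.5 else cells
  or <- (adj[["a"]] * adj[["d"]]) / (adj[["b"]] * adj[["c"]])
  se <- sqrt(sum(1 / adj))
  list(or = unname(or),
       ci_lo = unname(or * exp(-qnorm(0.975) * se)),
       ci_hi = unname(or * exp(qnorm(0.975) * se)),
       table = cells, corrected = corrected)
}
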