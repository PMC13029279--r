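# Linear embedding of z-standardised drug-level features with variance
# decomposition and leave-one-drug-out loading-stability diagnostics.

#' z-standardise a drug-by-feature matrix
#'
#' Centres each feature to mean 0 and scales to unit sample (n-1) standard
#' deviation. Constant features are dropped with a message.
#' @param x Numeric matrix or data frame (rows = drugs).
#' @return Standardised matrix; attribute `dropped` lists removed features.
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Standardisation requires at least 2 drugs.")
  sds <- apply(x, 2, sd)
  constant <- !is.finite(sds) | sds == 0
  if (all(constant)) abort("All features are constant.")
  dropped <- colnames(x)[constant]
  if (any(constant)) {
    inform(paste0("Constant feature(s) dropped: ",
                  paste(dropped, collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  structure(out, dropped = dropped)
}

# Fix component signs so the largest-magnitude loading per component is
# positive, making repeated runs bit-comparable.
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component embedding of standardised features
#'
#' PCA of a pre-standardised matrix; components ordered by variance, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). Variance fractions are taken over all
#' components, so they sum to 1.
#'
#' @param x Standardised matrix (from [zscore_features()]).
#' @param k Number of components to return (default 2; truncated to the
#'   matrix rank with a message if larger).
#' @return List of class `pca_embedding`: `loadings` (feature x component),
#'   `variance_frac` (length k), `variance_frac_all`, `scores`
#'   (drug x component), `feature_list`.
#' @export
pca_embed <- function(x, k = 2) {
  x <- as.matrix(x)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) {
    inform(sprintf("Requested k = %d components; rank is %d. Truncating.",
                   k, rank))
    k <- rank
  }
  frac_all <- pc$sdev^2 / sum(pc$sdev^2)
  fixed <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE],
                     pc$x[, seq_len(k), drop = FALSE])
  structure(list(
    loadings = fixed$loadings,
    variance_frac = frac_all[seq_len(k)],
    variance_frac_all = frac_all,
    scores = fixed$scores,
    feature_list = colnames(x)
  ), class = "pca_embedding")
}

#' Leave-one-drug-out loading stability
#'
#' For each drug, re-standardises and refits the embedding without it,
#' sign-aligns the refit loadings to the full-data loadings (by the sign of
#' their inner product), and reports the Pearson correlation per component.
#' Drugs whose refit fails (rank collapse) are flagged and excluded.
#'
#' @param x Raw (unstandardised) drug-by-feature matrix with >= 4 rows.
#' @param k Components to track (default 2).
#' @return Tibble `left_out` (row name or index), `component`, `r`.
#' @export
lodo_loading_stability <- function(x, k = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 4) abort("Leave-one-drug-out requires at least 4 drugs.")
  full <- pca_embed(zscore_features(x), k = k)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rows <- list()
  for (i in seq_len(nrow(x))) {
    refit <- tryCatch(
      suppressMessages(pca_embed(zscore_features(x[-i, , drop = FALSE]), k = k)),
      error = function(e) NULL
    )
    if (is.null(refit) || ncol(refit$loadings) < k) {
      warn(sprintf("Refit without drug '%s' failed; excluded.", ids[i]))
      next
    }
    common <- intersect(rownames(full$loadings), rownames(refit$loadings))
    for (j in seq_len(k)) {
      a <- full$loadings[common, j]
      b <- refit$loadings[common, j]
      if (sum(a * b) < 0) b <- -b
      rows[[length(rows) + 1L]] <- tibble::tibble(
        left_out = ids[i], component = paste0("PC", j), r = cor(a, b))
    }
  }
  dplyr::bind_rows(rows)
}

#' Assemble the drug-level embedding feature matrix
#'
#' Two feature sets are supported: `"mixed"` (polypharmacy, network
#' topology, reporting breadth, and mean continuous ADMET predictors) and
#' `"admet_only"` (continuous ADMET predictors alone).
#'
#' @param summary Drug-level summary from [drug_level_summary()].
#' @param admet ADMET table.
#' @param feature_set `"mixed"` or `"admet_only"`.
#' @return Numeric matrix with drugs as row names.
#' @export
embedding_features <- function(summary, admet,
                               feature_set = c("mixed", "admet_only")) {
  feature_set <- rlang::arg_match(feature_set)
  adm_cols <- intersect(c("ADMET_Risk", "BSEP_IC50", "hERG_pIC50",
                          "CYP_HLM_CLint"), names(admet))
  adm <- admet[match(summary$drug, admet$drug), adm_cols, drop = FALSE]
  adm <- median_impute(adm)
  base <- if (feature_set == "mixed") {
    cbind(mean_polypharmacy = summary$mean_polypharmacy,
          mean_degree = summary$degree,
          mean_betweenness = summary$betweenness,
          total_reports = summary$total_reports,
          n_clusters = summary$n_clusters,
          as.matrix(adm))
  } else {
    as.matrix(adm)
  }
  rownames(base) <- summary$drug
  base
}
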