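scored_fixture <- function() {
  coh <- std_cohort(n_cases = 600, seed = 11)
  map <- harmonise_phenotypes(coh$cases)
  graph <- build_comed_graph(coh$cases)
  admet <- generate_admet_table(coh$catalog, seed = 11)
  list(coh = coh, map = map, graph = graph, admet = admet,
       mvi = mvi_table(coh$cases, map, graph, admet, seed = 11))
}

test_that("the burden composite is the volume-by-breadth product", {
  expect_equal(adr_composite(10, 2), 20)
  expect_equal(adr_composite(0, 7), 0)
  expect_equal(adr_composite(c(3, 4), c(2, 5)), c(6, 20))
  fx <- scored_fixture()
  # recount oracle: per-drug case volume times distinct phenotype count
  long <- tidyr::separate_rows(
    dplyr::transmute(apply_phenotype_map(fx$coh$cases, fx$map),
                     case_id = case_id, drug = suspect_actives,
                     phenotype = phenotype),
    "drug", sep = ";")
  recount <- dplyr::summarise(
    dplyr::group_by(long, drug),
    expected = dplyr::n_distinct(case_id) * dplyr::n_distinct(phenotype),
    .groups = "drop")
  joined <- dplyr::left_join(fx$mvi, recount, by = "drug")
  expect_equal(joined$adr_composite, joined$expected)
})

test_that("high-burden labelling uses the inclusive type-7 upper quartile", {
  # 1..8: Q0.75 = 6.25, so 7 and 8 are labelled
  expect_equal(sum(label_high_burden(1:8)), 2)
  expect_true(all(label_high_burden(rep(4, 6)))) # all-ties degenerate
  # strictly increasing 1..100: Q0.75 = 75.25, so 76..100 are labelled
  expect_equal(sum(label_high_burden(1:100)), 25)
  expect_error(label_high_burden(1:3), "at least 4")
  # invariant to row order
  v <- c(5, 1, 9, 2, 8, 3)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(label_high_burden(v)[perm], label_high_burden(v[perm]))
})

test_that("the random forest separates separable labels and not permuted ones", {
  set.seed(7)
  n <- 40
  feat <- tibble::tibble(drug = sprintf("d%02d", 1:n),
                         x1 = rnorm(n), x2 = rnorm(n))
  labels <- feat$x1 > 0
  rf <- fit_rf_high_burden(feat, labels, seed = 1, exclude = character(0))
  expect_true(all(rf$rf_prob >= 0 & rf$rf_prob <= 1))
  expect_gt(suppressMessages(pROC::auc(pROC::roc(labels, rf$rf_prob, quiet = TRUE))), 0.95)
  # permuted labels: no signal on average (single-permutation OOB AUC is
  # noisy at n = 40, so average over permutations)
  auc0 <- mean(vapply(1:10, function(s) {
    perm <- sample(labels)
    rf0 <- fit_rf_high_burden(feat, perm, seed = s, exclude = character(0))
    pregvig:::auc_quiet(perm, rf0$rf_prob)
  }, numeric(1)))
  expect_lt(abs(auc0 - 0.5), 0.15)
  # deterministic per seed; single-class labels rejected
  rf2 <- fit_rf_high_burden(feat, labels, seed = 1, exclude = character(0))
  expect_identical(rf$rf_prob, rf2$rf_prob)
  expect_error(fit_rf_high_burden(feat, rep(TRUE, n)), "classes")
})

test_that("median imputation fills missing predictors before fitting", {
  feat <- tibble::tibble(drug = letters[1:8],
                         x1 = c(1, 2, NA, 4, 5, NA, 7, 8),
                         x2 = 1:8)
  labels <- c(rep(FALSE, 4), rep(TRUE, 4))
  expect_silent(rf <- fit_rf_high_burden(feat, labels, seed = 2,
                                         exclude = character(0)))
  expect_false(anyNA(rf$rf_prob))
})

test_that("the composite score reads off its weights", {
  expect_equal(composite_raw(1, 0, 0, 0), 0.60)
  expect_equal(composite_raw(0, 1, 1, 1), 0.40)
  set.seed(3)
  p <- runif(10); z1 <- rnorm(10); z2 <- rnorm(10); z3 <- rnorm(10)
  w <- c(0.3, 0.3, 0.2, 0.2)
  expect_equal(composite_raw(p, z1, z2, z3, w),
               cbind(p, z1, z2, z3) %*% w |> as.vector())
  expect_error(composite_raw(1, 0, 0, 0, weights = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("the percentile transform reproduces the published 25-drug grid", {
  set.seed(9)
  scores <- rnorm(25)
  pct <- mvi_percentile(scores)
  ranked <- sort(pct, decreasing = TRUE)
  expect_equal(round(ranked[1:3], 1), c(100.0, 95.8, 91.7))
  expect_equal(min(pct), 0)
  # consecutive tie-free ranks are exactly 100/24 apart
  expect_equal(unique(round(diff(sort(pct)), 10)), round(100 / 24, 10))
  # ties share the average rank: two tied maxima among 3 -> both 75
  expect_equal(mvi_percentile(c(1, 2, 2)), c(0, 75, 75))
  expect_warning(one <- mvi_percentile(5), "Single")
  expect_equal(one, 100)
})

test_that("the percentile transform is strictly monotone on tie-free scores", {
  set.seed(4)
  s <- sample(seq(-3, 3, length.out = 40))
  pct <- mvi_percentile(s)
  expect_equal(order(pct), order(s))
  expect_equal(rank(pct), rank(s))
})

test_that("the MVI table wires components coherently on a synthetic cohort", {
  fx <- scored_fixture()
  mvi <- fx$mvi
  expect_true(all(mvi$rf_prob >= 0 & mvi$rf_prob <= 1))
  expect_true(all(mvi$mvi_pct >= 0 & mvi$mvi_pct <= 100))
  expect_equal(mvi$adr_composite, mvi$total_reports * mvi$n_clusters)
  expect_equal(mean(mvi$z_poly), 0, tolerance = 1e-9)
  # percentile is a monotone transform of the composite
  expect_equal(order(mvi$mvi_pct), order(mvi$composite_raw))
  # label constituents excluded from the forest by default
  expect_false(any(c("total_reports", "n_clusters") %in%
                     attr(attr(mvi, "rf"), "feature_names")))
})

test_that("weight perturbations leave the ranking broadly stable", {
  fx <- scored_fixture()
  mvi <- fx$mvi
  set.seed(12)
  ok <- 0L
  for (i in 1:25) {
    w <- c(0.60, 0.15, 0.15, 0.10) + runif(4, -0.05, 0.05)
    w <- pmax(w, 0); w <- w / sum(w)
    alt <- composite_raw(mvi$rf_prob, mvi$z_poly, mvi$z_net, mvi$z_sev, w)
    rho <- cor(mvi$composite_raw, alt, method = "spearman")
    if (rho >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.95 * 25))
})

test_that("MVI diagnostics return the documented shape and sane values", {
  fx <- scored_fixture()
  diag <- mvi_diagnostics(fx$mvi, B = 30, seed = 2, n_trees = 150)
  expect_named(diag, c("holdout_auc", "lodo_auc", "oob_error", "bootstrap",
                       "importance_cv", "weight_rank_stability", "vif"),
               ignore.order = TRUE)
  expect_true(is.na(diag$lodo_auc) || (diag$lodo_auc >= 0 && diag$lodo_auc <= 1))
  expect_true(diag$oob_error >= 0 && diag$oob_error <= 1)
  expect_equal(nrow(diag$bootstrap$per_drug), nrow(fx$mvi))
  expect_true(all(diag$vif >= 1))
  # identical weights compared to themselves give perfect rank agreement
  same <- mvi_diagnostics(fx$mvi, B = 2, seed = 2, n_trees = 50,
                          alt_weights = c(0.60, 0.15, 0.15, 0.10))
  expect_equal(same$weight_rank_stability$spearman, 1)
  expect_equal(same$weight_rank_stability$kendall, 1)
  expect_error(mvi_diagnostics(fx$mvi, B = 1), "at least 2")
})

test_that("orthogonal components produce variance inflation factors near 1", {
  set.seed(5)
  # orthogonalise against the intercept too, so pairwise partial R^2 is 0
  x <- qr.Q(qr(cbind(1, matrix(rnorm(100), 25, 4))))[, -1]
  colnames(x) <- c("rf_prob", "z_poly", "z_net", "z_sev")
  v <- pregvig:::vif_components(as.data.frame(x))
  expect_true(all(abs(v - 1) < 1e-8))
})

test_that("the DPS combines overlap, amplification and vulnerability", {
  admet <- tibble::tibble(
    drug = c("a", "b", "c", "d"),
    flag_Pgp_inhibitor = c(TRUE, TRUE, FALSE, FALSE),
    flag_Pgp_substrate = c(TRUE, FALSE, FALSE, FALSE),
    flag_BCRP_substrate = c(FALSE, FALSE, FALSE, FALSE),
    flag_BSEP_inhibitor = c(TRUE, TRUE, FALSE, FALSE)
  )
  centrality <- tibble::tibble(drug = c("a", "b", "c", "d"),
                               degree = c(10, 8, 0, 0), betweenness = 0)
  mvi <- tibble::tibble(drug = c("a", "b", "c", "d"),
                        mvi_pct = c(100, 100, 0, 0))
  regimens <- tibble::tibble(regimen = c("a;b", "c;d"), n_reports = c(3, 2))
  out <- dps_table(regimens, admet, centrality, mvi)
  # regimen a;b shares Pgp-inhibition and BSEP-inhibition: 2 of 4 axes
  expect_equal(out$mos[1], 0.5)
  expect_equal(out$mos[2], 0)
  # NAS percent ranks: a;b has the larger summed degree
  expect_equal(out$nas, c(1, 0))
  expect_equal(out$svs, c(1, 0))
  expect_equal(out$dps[2], 0)
  expect_equal(out$tier[2], "3-low")
  expect_equal(out$dps[1], (0.5 + 1 + 1) / 3)
  expect_equal(out$tier[1], "1-high")
  expect_error(dps_table(tibble::tibble(regimen = "a"), admet, centrality, mvi),
               "at least 2")
})

test_that("regimen derivation returns unique multi-drug suspect sets", {
  cases <- micro_cases()
  reg <- derive_regimens(cases)
  expect_equal(reg$regimen, "drugA;drugB")
  expect_equal(reg$n_reports, 1)
  fx <- scored_fixture()
  regs <- derive_regimens(fx$coh$cases)
  expect_true(all(lengths(strsplit(regs$regimen, ";")) >= 2))
  expect_false(any(duplicated(regs$regimen)))
})

test_that("a fully shared, hub-heavy, max-vulnerability regimen tops the tiers", {
  admet <- tibble::tibble(
    drug = c("a", "b", "c", "d"),
    flag_Pgp_inhibitor = TRUE, flag_Pgp_substrate = TRUE,
    flag_BCRP_substrate = TRUE, flag_BSEP_inhibitor = TRUE
  )
  centrality <- tibble::tibble(drug = c("a", "b", "c", "d"),
                               degree = c(50, 50, 1, 1), betweenness = 0)
  mvi <- tibble::tibble(drug = c("a", "b", "c", "d"),
                        mvi_pct = c(100, 100, 50, 50))
  regimens <- tibble::tibble(regimen = c("a;b", "c;d"), n_reports = 1:2)
  out <- dps_table(regimens, admet, centrality, mvi)
  expect_equal(out$dps[1], 1)
  expect_equal(out$tier[1], "1-high")
})
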