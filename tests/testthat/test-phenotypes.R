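test_that("harmonisation collapses sub-threshold labels into Other", {
  freqs <- c(A = 0.5, B = 0.3, C = 0.15, D = 0.04, E = 0.01)
  cases <- tibble::tibble(raw_cluster = rep(names(freqs), freqs * 200),
                          serious = TRUE)
  map <- harmonise_phenotypes(cases, threshold_frac = 0.02)
  expect_equal(map$harmonised[map$raw == "E"], "Other")
  expect_equal(map$harmonised[map$raw != "E"], c("A", "B", "C", "D"))
  # all labels at/above threshold -> identity, no Other
  map2 <- harmonise_phenotypes(cases[cases$raw_cluster != "E", ], 0.02)
  expect_false("Other" %in% map2$harmonised)
  expect_error(harmonise_phenotypes(cases, 0), "between 0 and 1")
  expect_error(harmonise_phenotypes(cases, 1), "between 0 and 1")
})

test_that("harmonisation conserves case counts and yields five phenotypes on a study-shaped cohort", {
  coh <- std_cohort(n_cases = 2000, seed = 21)
  map <- harmonise_phenotypes(coh$cases)
  expect_equal(sum(map$frequency), 1, tolerance = 1e-9)
  harmonised <- apply_phenotype_map(coh$cases, map)$phenotype
  expect_equal(length(harmonised), nrow(coh$cases))
  expect_equal(sort(unique(harmonised)), c("C1", "C2", "C3", "C5", "Other"))
})

test_that("seriousness by phenotype computes fractions and stability flags", {
  cases <- tibble::tibble(
    raw_cluster = c(rep("A", 4), "B"),
    serious = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  map <- tibble::tibble(raw = c("A", "B"), harmonised = c("A", "B"),
                        frequency = c(0.8, 0.2))
  out <- seriousness_by_phenotype(cases, map)
  expect_equal(out$serious_frac[out$phenotype == "A"], 0.75)
  expect_equal(out$serious_frac[out$phenotype == "B"], 1.0)
  expect_false(out$stability_flag[out$phenotype == "B"]) # single case
  expect_false(out$stability_flag[out$phenotype == "A"]) # 4 < default floor 5
})

test_that("signature z-scores standardise medians across phenotypes and flag constants", {
  expanded <- tibble::tibble(
    case_id = c("1", "2"), drug = c("d1", "d2"), reaction = "r",
    cluster = c("A", "B"), serious = TRUE
  )
  admet <- tibble::tibble(drug = c("d1", "d2"), ADMET_Risk = c(1, 3),
                          TOX_Risk = c(2, 2))
  map <- tibble::tibble(raw = c("A", "B"), harmonised = c("A", "B"),
                        frequency = 0.5)
  sig <- admet_signature(expanded, admet, map,
                         features = c("ADMET_Risk", "TOX_Risk"))
  # medians 1 and 3: mean 2, sample SD sqrt(2) -> z = (-0.707, +0.707)
  expect_equal(unname(sig[, "ADMET_Risk"]), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(sig[, "TOX_Risk"]), c(0, 0))
  expect_equal(attr(sig, "constant_features"), "TOX_Risk")
  tidy <- signature_tidy(sig)
  expect_equal(nrow(tidy), 4)
})

test_that("an extreme phenotype among five attains the maximal sample z of 1.79", {
  expanded <- tibble::tibble(
    case_id = as.character(1:5), drug = paste0("d", 1:5), reaction = "r",
    cluster = LETTERS[1:5], serious = TRUE
  )
  admet <- tibble::tibble(drug = paste0("d", 1:5),
                          ADMET_Risk = c(0, 0, 0, 0, 10))
  map <- tibble::tibble(raw = LETTERS[1:5], harmonised = LETTERS[1:5],
                        frequency = 0.2)
  sig <- admet_signature(expanded, admet, map, features = "ADMET_Risk")
  expect_equal(max(sig[, 1]), 4 / sqrt(5), tolerance = 1e-12)
  expect_equal(round(max(sig[, 1]), 2), 1.79)
})

test_that("Kruskal-Wallis panel matches brute-force rank arithmetic", {
  # 3 groups of 3 values, with a tie
  values <- c(1.2, 3.4, 2.2, 5.1, 4.4, 5.1, 0.3, 2.8, 6.0)
  groups <- rep(c("A", "B", "C"), each = 3)
  kt <- kruskal.test(values, factor(groups))
  expect_equal(unname(kt$statistic), kw_h_brute(values, groups),
               tolerance = 1e-12)
  # the panel wires the same statistic through the phenotype mapping
  expanded <- tibble::tibble(case_id = as.character(1:9),
                             drug = paste0("d", 1:9), reaction = "r",
                             cluster = groups, serious = TRUE)
  admet <- tibble::tibble(drug = paste0("d", 1:9), ADMET_Risk = values)
  map <- tibble::tibble(raw = c("A", "B", "C"), harmonised = c("A", "B", "C"),
                        frequency = 1 / 3)
  panel <- kw_panel(expanded, admet, map, features = "ADMET_Risk")
  expect_equal(panel$H, kw_h_brute(values, groups), tolerance = 1e-12)
  expect_equal(panel$q, panel$p) # single-feature panel
})

test_that("two-group Kruskal-Wallis equals the rank-sum chi-square form", {
  values <- c(5, 8, 1, 9, 3, 7, 2)
  groups <- c("A", "A", "A", "B", "B", "B", "B")
  expect_equal(unname(kruskal.test(values, factor(groups))$statistic),
               kw_h_brute(values, groups), tolerance = 1e-12)
})

test_that("ICC(1) matches hand ANOVA arithmetic and handles edge cases", {
  # balanced 2 groups x 3 observations
  values <- c(1, 2, 3, 7, 8, 9)
  groups <- rep(c("g1", "g2"), each = 3)
  grand <- mean(values)
  msb <- sum(3 * (tapply(values, groups, mean) - grand)^2) / 1
  msw <- sum((values - rep(tapply(values, groups, mean), each = 3))^2) / 4
  out <- icc_one_way(values, groups)
  expect_equal(out$k0, 3)
  expect_equal(out$icc, (msb - msw) / (msb + 2 * msw), tolerance = 1e-12)
  # zero within-group variance, distinct means -> 1
  expect_equal(icc_one_way(c(1, 1, 5, 5), c("a", "a", "b", "b"))$icc, 1)
  # equal group means, within variance > 0 -> truncated to ~0
  expect_equal(icc_one_way(c(1, 3, 1, 3), c("a", "a", "b", "b"))$icc, 0)
  # identical observations -> defined 0 with flag
  deg <- icc_one_way(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(deg$icc, 0)
  expect_true(deg$degenerate)
  expect_error(icc_one_way(1:5, rep("a", 5)), "2 groups")
})

test_that("ICC(1) recovers the simulated variance ratio", {
  sigma_b2 <- 1
  sigma_w2 <- 3
  target <- sigma_b2 / (sigma_b2 + sigma_w2)
  set.seed(42)
  est <- replicate(10, {
    groups <- rep(seq_len(50), each = 20)
    values <- rnorm(50, 0, sqrt(sigma_b2))[groups] +
      rnorm(1000, 0, sqrt(sigma_w2))
    icc_one_way(values, groups)$icc
  })
  expect_lt(abs(mean(est) - target), 0.05)
})

test_that("reaction-class odds ratio follows the cross-product with zero-cell correction", {
  # build cases so the 2x2 table is (20, 10, 5, 40)
  cases <- tibble::tibble(
    raw_cluster = c(rep("P", 30), rep("Q", 45)),
    reactions = c(rep("cholestasis", 20), rep("rash", 10),
                  rep("cholestasis", 5), rep("rash", 40)),
    serious = TRUE
  )
  map <- tibble::tibble(raw = c("P", "Q"), harmonised = c("P", "Q"),
                        frequency = c(0.4, 0.6))
  out <- reaction_class_or(cases, map, "cholestasis", "P")
  expect_equal(out$or, 16)
  expect_false(out$corrected)
  expect_lt(out$ci_lo, 16)
  expect_gt(out$ci_hi, 16)
  # a zero cell: correction keeps the OR finite and flags it
  cases0 <- cases[cases$raw_cluster == "Q" | cases$reactions == "cholestasis", ]
  out0 <- reaction_class_or(cases0, map, "cholestasis", "P")
  expect_true(out0$corrected)
  expect_true(is.finite(out0$or))
  expect_error(reaction_class_or(cases, map, character(0), "P"), "non-empty")
  expect_error(reaction_class_or(cases, map, "cholestasis", "Z"), "no cases")
})

test_that("planted signature shifts are recovered in sign across seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    coh <- generate_cohort(synth_config(n_cases = 800, seed = 1000 + s))
    shifts <- matrix(0, 1, 1, dimnames = list("C3", "BSEP_IC50"))
    shifts["C3", "BSEP_IC50"] <- 2
    admet <- generate_admet_table(coh$catalog, shifts = shifts,
                                  missing_frac = 0, noise_sd = 0.5,
                                  seed = 2000 + s)
    expanded <- suppressMessages(expand_cases(coh$cases))
    map <- harmonise_phenotypes(coh$cases)
    sig <- admet_signature(expanded, admet, map, features = "BSEP_IC50")
    if (rownames(sig)[which.max(sig[, 1])] == "C3") hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_seeds))
})
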