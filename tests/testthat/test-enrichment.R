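micro_map <- function() {
  tibble::tibble(raw = c("P1", "P2"), harmonised = c("P1", "P2"),
                 frequency = 0.5)
}

test_that("contingency tables are built at case level under both attributions", {
  cases <- micro_cases()
  map <- micro_map()
  catalog <- micro_catalog()
  prim <- drug_phenotype_tables(cases, map, catalog, "primary")
  # every table sums to the number of cases
  expect_true(all(prim$a + prim$b + prim$c + prim$d == nrow(cases)))
  # primary attribution partitions the cohort: sum of a over drugs, within a
  # phenotype column, equals the phenotype count; over all cells, n_cases
  expect_equal(sum(prim$a), nrow(cases))
  # all-suspect: case c2 (drugA + drugB) contributes to both drugs' tables
  alls <- drug_phenotype_tables(cases, map, catalog = NULL, "all_suspect")
  a_drugA <- sum(alls$a[alls$drug == "drugA"])
  expect_equal(a_drugA, 2) # cases c1 and c2
  expect_error(drug_phenotype_tables(cases, map, catalog, "bogus"))
})

test_that("a perfectly aligned drug-phenotype pair gives the diagonal table", {
  cases <- tibble::tibble(
    case_id = as.character(1:4),
    suspect_actives = c("X", "X", "Y", "Y"),
    concomitant_actives = "", reactions = "r",
    serious = TRUE, sex = "F", follow_up = FALSE, literature = FALSE,
    raw_cluster = c("P", "P", "Q", "Q")
  )
  map <- tibble::tibble(raw = c("P", "Q"), harmonised = c("P", "Q"),
                        frequency = 0.5)
  tabs <- drug_phenotype_tables(cases, map, catalog = NULL, "all_suspect")
  xp <- tabs[tabs$drug == "X" & tabs$phenotype == "P", ]
  expect_equal(unlist(xp[c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 0, 0, 2))
})

test_that("ROR follows the cross-product and symmetric tables give p = 1", {
  out <- ror_fisher(5, 5, 5, 5)
  expect_equal(out$ror, 1)
  expect_equal(out$p, 1)
  expect_equal(ror_fisher(10, 5, 20, 100)$ror, 10)
  expect_error(ror_fisher(0, 0, 0, 0), "All-zero")
  # zero cell: Haldane-Anscombe on all cells, flagged
  z <- ror_fisher(2, 0, 0, 2)
  expect_true(z$corrected)
  expect_equal(z$ror, (2.5 * 2.5) / (0.5 * 0.5))
})

test_that("ROR is invariant to swapping b and c, and inverts when rows swap", {
  out <- ror_fisher(7, 3, 11, 19)
  swapped <- ror_fisher(7, 11, 3, 19)
  expect_equal(out$ror, swapped$ror)
  rows <- ror_fisher(11, 19, 7, 3)
  expect_equal(rows$ror, 1 / out$ror, tolerance = 1e-12)
  # Fisher p invariant under row and column exchange
  expect_equal(out$p, rows$p, tolerance = 1e-12)
  expect_equal(out$p, ror_fisher(3, 7, 19, 11)$p, tolerance = 1e-12)
})

test_that("Fisher p agrees with hypergeometric enumeration on small tables", {
  set.seed(1)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    p <- ror_fisher(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(p, fisher_p_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("BH q-values match the hand step-up and respect edge cases", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_fdr(p), bh_manual(p), tolerance = 1e-12)
  expect_true(all(bh_fdr(p) >= p))
  expect_message(q <- bh_fdr(c(0.5, NA, 0.01)), "NA p-value")
  expect_true(is.na(q[2]))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("O/E enrichment equals observed over independence expectation", {
  expect_equal(oe_enrichment(1, 1, 1, 1), 1)
  expect_equal(oe_enrichment(2, 0, 0, 2), 2)
  expect_equal(oe_enrichment(0, 2, 2, 0), 0)
  expect_message(na <- oe_enrichment(0, 0, 5, 5), "Zero margin")
  expect_true(is.na(na))
})

test_that("the enrichment panel flags q < 0.05 with ROR > 1 only", {
  coh <- std_cohort(n_cases = 600, seed = 11)
  map <- harmonise_phenotypes(coh$cases)
  panel <- suppressMessages(
    enrichment_panel(coh$cases, map, coh$catalog, "primary"))
  expect_true(all(panel$enriched == (!is.na(panel$q) & panel$q < 0.05 & panel$ror > 1)))
  expect_true(all(panel$a + panel$b + panel$c + panel$d == nrow(coh$cases)))
  # partition identity: each case lands in exactly one (primary drug,
  # phenotype) cell, so the a counts sum to the cohort size
  expect_equal(sum(panel$a), nrow(coh$cases))
})

test_that("under a decoupled generator the q < 0.05 false positive rate is controlled", {
  # no drug-phenotype linkage: enrichment discoveries are false by design
  n_panels <- 40
  fp <- 0L
  tot <- 0L
  for (s in seq_len(n_panels)) {
    coh <- generate_cohort(synth_config(n_cases = 250, phenotype_coupling = 0.5,
                                        seed = 5000 + s))
    map <- harmonise_phenotypes(coh$cases)
    panel <- suppressMessages(
      enrichment_panel(coh$cases, map, coh$catalog, "primary"))
    fp <- fp + sum(panel$q < 0.05, na.rm = TRUE)
    tot <- tot + sum(!is.na(panel$q))
  }
  se <- sqrt(0.05 * 0.95 / tot)
  expect_lte(fp / tot, 0.05 + 3 * se)
})

test_that("attribution sensitivity reports top-k Jaccard per phenotype", {
  mk <- function(drugs, oe) {
    tibble::tibble(drug = drugs, phenotype = "P", oe_ratio = oe,
                   q = seq_along(drugs) / 100)
  }
  ten <- sprintf("d%02d", 1:10)
  # identical rankings -> 1.0
  same <- suppressMessages(attribution_sensitivity(mk(ten, 10:1), mk(ten, 10:1)))
  expect_equal(same$jaccard, 1)
  # disjoint top-10 sets -> 0.0
  other <- sprintf("e%02d", 1:10)
  both <- dplyr::bind_rows(mk(ten, 10:1), mk(other, rep(0.1, 10)))
  flip <- dplyr::bind_rows(mk(ten, rep(0.1, 10)), mk(other, 10:1))
  disjoint <- suppressMessages(attribution_sensitivity(both, flip))
  expect_equal(disjoint$jaccard, 0)
  # 6 shared of union 14 -> 6/14
  a <- mk(c(ten[1:6], sprintf("x%d", 1:4)), 10:1)
  b <- mk(c(ten[1:6], sprintf("y%d", 1:4)), 10:1)
  mixed <- suppressMessages(attribution_sensitivity(a, b))
  expect_equal(mixed$jaccard, 6 / 14)
})

test_that("the synthetic cohort's primary and all-suspect rankings broadly agree", {
  coh <- std_cohort(n_cases = 600, seed = 11)
  map <- harmonise_phenotypes(coh$cases)
  prim <- suppressMessages(enrichment_panel(coh$cases, map, coh$catalog, "primary"))
  alls <- suppressMessages(enrichment_panel(coh$cases, map, coh$catalog, "all_suspect"))
  jac <- suppressMessages(attribution_sensitivity(prim, alls))
  expect_true(all(jac$jaccard >= 0 & jac$jaccard <= 1))
  expect_gt(mean(jac$jaccard), 0.3)
})
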