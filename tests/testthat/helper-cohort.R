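# Shared fixtures, built in code.  `std_cohort()` memoises a mid-sized
# synthetic cohort reused across test files.

.cohort_cache <- new.env(parent = emptyenv())

std_cohort <- function(n_cases = 600, seed = 11, ...) {
  key <- paste0("c", n_cases, "_", seed, "_", rlang::hash(list(...)))
  if (is.null(.cohort_cache[[key]])) {
    cfg <- synth_config(n_cases = n_cases, seed = seed, ...)
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

# Hand-built four-case micro-cohort with known structure.
micro_cases <- function() {
  tibble::tibble(
    case_id = c("c1", "c2", "c3", "c4"),
    suspect_actives = c("drugA", "drugA;drugB", "drugB", "drugC"),
    concomitant_actives = c("comedX", "", "comedX;comedY", ""),
    reactions = c("nausea;cholestasis", "nausea", "rash", "cholestasis"),
    serious = c(TRUE, FALSE, TRUE, TRUE),
    sex = c("F", "F", "M", "F"),
    follow_up = c(FALSE, TRUE, FALSE, FALSE),
    literature = c(FALSE, FALSE, FALSE, TRUE),
    raw_cluster = c("P1", "P1", "P2", "P2")
  )
}

micro_catalog <- function() {
  tibble::tibble(
    drug = c("drugA", "drugB", "drugC", "comedX", "comedY"),
    drug_class = c("NRTI", "PI", "INSTI", "other", "other"),
    suspect_eligible = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    is_booster = FALSE,
    home_cluster = c("P1", "P1", "P2", "P1", "P2"),
    popularity = c(1, 1, 1, NA, NA),
    hub_weight = 1,
    mw = c(300, 500, 400, 250, 350)
  )
}

# Independent brute-force two-sided Fisher exact p for a 2x2 table with
# fixed margins, by hypergeometric enumeration (same <= rule, with the
# customary relative tolerance, as the classical test).
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b
  n_ <- c + d
  k <- a + c
  lo <- max(0, k - n_)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent tie-corrected Kruskal-Wallis H by direct rank arithmetic.
kw_h_brute <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  groups <- factor(groups)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Hand step-up BH.
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
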