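# Internal helpers shared across modules.

# Validate that a named numeric vector is a probability vector.
check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be a non-negative numeric vector without NA.", what))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", what, sum(p)))
  }
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    abort(sprintf("`%s` must be fully named.", what))
  }
  invisible(p)
}

# Derive a stream of child seeds from one parent seed; restores the caller's
# RNG state.  Every derived seed stays in 32-bit range.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  with_seed((as.integer(seed) + as.integer(salt)) %% .Machine$integer.max,
            sample.int(.Machine$integer.max - 1L, n))
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Split a ";"-joined multi-valued cell into a character vector of unique,
# trimmed entries (empty cells give character(0)).
split_cell <- function(x, sep = ";") {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  unique(out[nzchar(out)])
}

join_cell <- function(x, sep = ";") paste(sort(unique(x)), collapse = sep)

# Population-scaled (divide by n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# z-score a vector; constant vectors map to 0 (caller may flag them).
zscore <- function(x, population = FALSE) {
  s <- if (population) sd_pop(x) else sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Area under the ROC curve via pROC, silenced.
auc_quiet <- function(labels, probs) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE, direction = "<",
                                 levels = c(FALSE, TRUE))))
}
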