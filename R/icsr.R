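# Case-level and expanded ICSR representations: deduplication, structural
# expansion, primary-active assignment, polypharmacy accounting, and the
# delimited-text interfaces for both tables.

CASE_COLUMNS <- c("case_id", "suspect_actives", "concomitant_actives",
                  "reactions", "serious", "sex", "follow_up", "literature",
                  "raw_cluster")

#' Validate a case-level table
#'
#' Checks the schema of a deduplicated case table and reports row-level
#' problems: missing columns, empty case ids, empty suspect sets, duplicate
#' ids.
#' @param cases Case-level tibble.
#' @return Invisibly `cases`; aborts with row-level messages on failure.
#' @export
validate_cases <- function(cases) {
  missing <- setdiff(CASE_COLUMNS, names(cases))
  if (length(missing)) {
    abort(paste0("Case table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  problems <- character(0)
  bad_id <- which(is.na(cases$case_id) | !nzchar(cases$case_id))
  if (length(bad_id)) {
    problems <- c(problems, sprintf("row %d: empty case_id", head(bad_id, 5)))
  }
  bad_sus <- which(is.na(cases$suspect_actives) | !nzchar(cases$suspect_actives))
  if (length(bad_sus)) {
    problems <- c(problems, sprintf("row %d: no suspect actives", head(bad_sus, 5)))
  }
  dup <- which(duplicated(cases$case_id))
  if (length(dup)) {
    problems <- c(problems, sprintf("row %d: duplicate case_id '%s'",
                                    head(dup, 5), cases$case_id[head(dup, 5)]))
  }
  if (length(problems)) {
    abort(c("Case table failed validation:", problems))
  }
  invisible(cases)
}

#' Deduplicate a raw record stream into one row per case
#'
#' Collapses a line-listing export (possibly several rows per case id, as in
#' reaction/drug-expanded exports) into one `CaseReport` row per distinct id.
#' Multi-valued fields are set-unions across the id's rows; seriousness is
#' the logical OR; for conflicting sex values the first-seen value wins with
#' a warning.
#'
#' @param rows Tibble of raw rows carrying at least `case_id`; multi-valued
#'   cells joined with `sep`.
#' @param sep Intra-cell separator (default `";"`).
#' @return Deduplicated case-level tibble (one row per id).
#' @export
deduplicate_cases <- function(rows, sep = ";") {
  if (!"case_id" %in% names(rows)) abort("`rows` must carry a `case_id` column.")
  if (any(is.na(rows$case_id) | !nzchar(rows$case_id))) {
    abort("Every row must carry a non-empty case id.")
  }
  union_join <- function(x) join_cell(unlist(lapply(x, split_cell, sep = sep)), sep = sep)
  first_or_na <- function(x) if (length(x)) x[[1]] else NA
  grouped <- dplyr::group_by(rows, .data$case_id)
  out <- dplyr::summarise(
    grouped,
    suspect_actives = union_join(.data$suspect_actives),
    concomitant_actives = if ("concomitant_actives" %in% names(rows)) {
      union_join(.data$concomitant_actives)
    } else "",
    reactions = union_join(.data$reactions),
    serious = any(.data$serious),
    sex = {
      vals <- unique(.data$sex[!is.na(.data$sex)])
      if (length(vals) > 1) {
        warn(sprintf("Conflicting sex values for case '%s'; first-seen ('%s') wins.",
                     dplyr::cur_group()$case_id, vals[1]))
      }
      first_or_na(vals)
    },
    follow_up = any(.data$follow_up),
    literature = any(.data$literature),
    raw_cluster = first_or_na(unique(.data$raw_cluster[!is.na(.data$raw_cluster)])),
    .groups = "drop"
  )
  validate_cases(out)
  out
}

#' Structurally expand cases into (case, drug, reaction) records
#'
#' One record per suspect drug x reaction term per case. Concomitant drugs
#' are excluded: mechanistic linkage is anchored to suspect drugs only, with
#' concomitants feeding polypharmacy and the co-medication network instead.
#' Cases with zero reactions emit zero records (logged via a message).
#'
#' @param cases Deduplicated case-level tibble.
#' @param sep Intra-cell separator.
#' @return Expanded tibble with columns `case_id`, `drug`, `reaction`,
#'   `cluster`, `serious`.
#' @export
expand_cases <- function(cases, sep = ";") {
  validate_cases(cases)
  empty <- !nzchar(cases$reactions) | is.na(cases$reactions)
  if (any(empty)) {
    inform(sprintf("%d case(s) with zero reactions emit no expanded records.",
                   sum(empty)))
  }
  out <- cases |>
    dplyr::transmute(case_id = .data$case_id, drug = .data$suspect_actives,
                     reaction = .data$reactions, cluster = .data$raw_cluster,
                     serious = .data$serious) |>
    tidyr::separate_rows("drug", sep = sep) |>
    tidyr::separate_rows("reaction", sep = sep) |>
    dplyr::filter(nzchar(.data$drug), nzchar(.data$reaction))
  tibble::as_tibble(out)
}

#' Assign the primary active drug by class hierarchy
#'
#' Among each case's suspect drugs, returns the drug whose class ranks
#' highest in the antiviral class priority INSTI > PI > NNRTI > NRTI > RdRp
#' (any other class ranks below RdRp). Ties within the top class are broken
#' by the lexicographically smallest drug name, making the assignment
#' deterministic and invariant to drug-list order.
#'
#' @param cases Case-level tibble (or a single-row tibble).
#' @param catalog Drug catalog with `drug` and `drug_class` columns covering
#'   every suspect drug.
#' @param sep Intra-cell separator.
#' @return Character vector of primary drugs, one per case.
#' @export
assign_primary_active <- function(cases, catalog, sep = ";") {
  sus_list <- lapply(cases$suspect_actives, split_cell, sep = sep)
  all_drugs <- unique(unlist(sus_list))
  unknown <- setdiff(all_drugs, catalog$drug)
  if (length(unknown)) {
    abort(paste0("Suspect drug(s) not in catalog: ", paste(unknown, collapse = ", ")))
  }
  cls <- catalog$drug_class[match(all_drugs, catalog$drug)]
  rank <- match(cls, CLASS_PRIORITY)
  rank[is.na(rank)] <- length(CLASS_PRIORITY) + 1L
  rank_of <- setNames(rank, all_drugs)
  vapply(sus_list, function(s) {
    s[order(rank_of[s], s)][1]
  }, character(1))
}

#' Polypharmacy accounting per case
#'
#' Counts unique active substances (suspect union concomitant) per case, the
#' number of concomitants, and whether a pharmacokinetic booster is present.
#'
#' @param cases Case-level tibble.
#' @param booster_list Actives treated as boosters.
#' @param sep Intra-cell separator.
#' @return Tibble with `case_id`, `poly_actives_total`, `n_concomitant`,
#'   `booster_present`.
#' @export
compute_polypharmacy <- function(cases,
                                 booster_list = c("ritonavir", "cobicistat"),
                                 sep = ";") {
  sus <- lapply(cases$suspect_actives, split_cell, sep = sep)
  con <- lapply(cases$concomitant_actives, split_cell, sep = sep)
  all <- Map(function(a, b) unique(c(a, b)), sus, con)
  tibble::tibble(
    case_id = cases$case_id,
    poly_actives_total = lengths(all),
    n_concomitant = lengths(con),
    booster_present = vapply(all, function(x) any(x %in% booster_list), logical(1))
  )
}

#' Read / write case-level tables
#'
#' Delimited-text interface with schema validation on load (row-level error
#' reports via [validate_cases()]).
#' @param path File path.
#' @param cases Case-level tibble.
#' @return `read_cases()` returns the validated tibble; `write_cases()`
#'   returns the path invisibly.
#' @export
read_cases <- function(path) {
  cases <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             case_id = "c", suspect_actives = "c",
                             concomitant_actives = "c", reactions = "c",
                             serious = "l", sex = "c", follow_up = "l",
                             literature = "l", raw_cluster = "c"
                           ))
  cases$concomitant_actives[is.na(cases$concomitant_actives)] <- ""
  cases$reactions[is.na(cases$reactions)] <- ""
  validate_cases(cases)
  cases
}

#' @rdname read_cases
#' @export
write_cases <- function(cases, path) {
  validate_cases(cases)
  readr::write_csv(cases, path)
  invisible(path)
}
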