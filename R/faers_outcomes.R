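#' Read adverse-event case records from JSON-lines
#'
#' One case per line, openFDA-dialect subset with fields `case_id` (text),
#' `is_duplicate` (logical), `country` (text code), `reactions` (array of ADR
#' term strings), `outcomes` (array of raw outcome codes; may be empty).
#'
#' @param path path to a JSON-lines file.
#' @return a `case_set`: data.frame with columns case_id, is_duplicate,
#'   country and list-columns reactions, outcomes.
#' @export
read_case_reports <- function(path) {
  if (!file.exists(path)) saedr_stop("case file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) saedr_stop("malformed JSON on line %d: %s",
                                            i, conditionMessage(e)))
  })
  as_case_set(recs)
}

#' Coerce a list of case records to a `case_set`
#'
#' Each record is a list with `case_id`, `is_duplicate`, `country`,
#' `reactions`, `outcomes` (see [read_case_reports()]).
#'
#' @param recs list of case-record lists.
#' @return a `case_set` data.frame.
#' @export
as_case_set <- function(recs) {
  df <- data.frame(
    case_id = vapply(recs, function(r) as.character(r$case_id %||% NA_character_), ""),
    is_duplicate = vapply(recs, function(r) isTRUE(r$is_duplicate), TRUE),
    country = vapply(recs, function(r) as.character(r$country %||% NA_character_), ""),
    stringsAsFactors = FALSE)
  df$reactions <- lapply(recs, function(r) as.character(unlist(r$reactions)))
  df$outcomes <- lapply(recs, function(r) as.character(unlist(r$outcomes)))
  class(df) <- c("case_set", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Normalize adverse-event case records
#'
#' Drops records missing a case ID (with a warning), removes records flagged
#' as duplicates, keeps the first occurrence per case ID, filters to the
#' requested reporting country, and lowercases reaction terms.  Cases left
#' with no reactions are removed.  Removal counts are logged and attached.
#'
#' @param raw a `case_set` (from [read_case_reports()] or [as_case_set()]).
#' @param country_filter reporting country to keep (default `"US"`);
#'   `NULL` disables the filter.
#' @param lexicon optional `lexicon`; reaction terms absent from it are
#'   counted as unmapped (retained, flagged in the attribute).
#' @return the normalized `case_set`, with attribute `removed` (named
#'   counts) and `n_unmapped_terms`.
#' @export
normalize_cases <- function(raw, country_filter = "US", lexicon = NULL) {
  stopifnot(inherits(raw, "case_set"))
  n0 <- nrow(raw)
  no_id <- is.na(raw$case_id) | !nzchar(raw$case_id)
  if (any(no_id)) {
    warning(sprintf("%d record(s) missing case_id rejected", sum(no_id)),
            call. = FALSE)
    raw <- raw[!no_id, , drop = FALSE]
  }
  dup_flag <- raw$is_duplicate
  raw <- raw[!dup_flag, , drop = FALSE]
  dup_id <- duplicated(raw$case_id)
  raw <- raw[!dup_id, , drop = FALSE]
  off_country <- 0L
  if (!is.null(country_filter)) {
    keep <- !is.na(raw$country) & raw$country == country_filter
    off_country <- sum(!keep)
    raw <- raw[keep, , drop = FALSE]
  }
  raw$reactions <- lapply(raw$reactions, tolower)
  empty <- lengths(raw$reactions) == 0L
  raw <- raw[!empty, , drop = FALSE]

  n_unmapped <- 0L
  if (!is.null(lexicon)) {
    all_rx <- unique(unlist(raw$reactions))
    n_unmapped <- sum(!all_rx %in% lexicon$records$term)
    if (n_unmapped > 0L) {
      saedr_log("%d distinct reaction term(s) not in lexicon (retained, flagged)",
                n_unmapped)
    }
  }
  removed <- c(missing_id = sum(no_id), duplicate = sum(dup_flag) + sum(dup_id),
               off_country = off_country, no_reactions = sum(empty))
  saedr_log("normalize_cases: %d -> %d cases (removed: %s)", n0, nrow(raw),
            paste(names(removed), removed, sep = "=", collapse = ", "))
  attr(raw, "removed") <- removed
  attr(raw, "n_unmapped_terms") <- n_unmapped
  raw
}

#' Map a raw case-outcome code to its normalized category
#'
#' Schema: Death -> `"Death"`; Life-Threatening, Hospitalization, Other
#' Serious, Required Intervention -> `"Serious Outcome"`; Congenital Anomaly,
#' Disability -> `"Disability"`.  An empty outcome list means the case has
#' category `"No Outcome"` (handled by the tabulation; this function maps
#' individual codes).  Unknown codes map to `"Unmapped"` and are excluded
#' from proportions.
#'
#' @param raw_code character vector of raw outcome codes.
#' @return character vector of categories.
#' @export
map_outcome <- function(raw_code) {
  schema <- c("Death" = "Death",
              "Life-Threatening" = "Serious Outcome",
              "Hospitalization" = "Serious Outcome",
              "Other Serious" = "Serious Outcome",
              "Required Intervention" = "Serious Outcome",
              "Congenital Anomaly" = "Disability",
              "Disability" = "Disability")
  out <- unname(schema[as.character(raw_code)])
  unknown <- is.na(out) & !is.na(raw_code)
  if (any(unknown)) {
    saedr_log("%d unmapped outcome code(s) (e.g. '%s')", sum(unknown),
              raw_code[unknown][1L])
    out[unknown] <- "Unmapped"
  }
  out
}

# internal: the set of normalized categories for one case.
# A case reporting several raw outcomes contributes once to each mapped
# category; an empty outcome list is the No Outcome category.
case_categories <- function(outcomes) {
  if (length(outcomes) == 0L) return("No Outcome")
  cats <- unique(map_outcome(outcomes))
  cats[cats != "Unmapped"]
}

#' Per-ADR outcome counts and proportions
#'
#' For every ADR term, counts the cases reporting it and, per normalized
#' outcome category, the cases in each category; the proportion divides by
#' the total cases reporting that ADR.  A multi-outcome case counts once per
#' mapped category, so category proportions can sum above 1.
#'
#' @param cases a normalized `case_set`.
#' @param min_reports drop ADRs with fewer cases than this from the returned
#'   table (default 0 = keep all).
#' @return An `outcome_table`: list with `table` (data.frame: adr_term,
#'   n_cases, n_death, p_death, n_serious, p_serious, n_disability,
#'   p_disability, n_none, p_none, n_death_serious), `n_cases` (total
#'   normalized cases) and `n_cases_death_serious` (cases whose categories
#'   include Death or Serious Outcome) — the inputs to
#'   [rank_from_outcomes()].
#' @export
outcome_proportions <- function(cases, min_reports = 0) {
  stopifnot(inherits(cases, "case_set"))
  n <- nrow(cases)
  cats <- lapply(cases$outcomes, case_categories)
  ds_case <- vapply(cats, function(cc) any(cc %in% c("Death", "Serious Outcome")), TRUE)

  rx <- cases$reactions
  nrx <- lengths(rx)
  adr <- unlist(rx)
  case_of <- rep(seq_len(n), nrx)
  # one (case, adr) pair even if a case repeats a reaction term
  pair <- !duplicated(paste0(case_of, "\r", adr))
  adr <- adr[pair]; case_of <- case_of[pair]

  cat_flags <- function(name) vapply(cats, function(cc) name %in% cc, TRUE)
  f_death <- cat_flags("Death"); f_serious <- cat_flags("Serious Outcome")
  f_disab <- cat_flags("Disability"); f_none <- cat_flags("No Outcome")

  tab <- data.frame(adr_term = sort(unique(adr)), stringsAsFactors = FALSE)
  cnt <- function(flag) {
    v <- tapply(flag[case_of], adr, sum)
    as.integer(v[tab$adr_term])
  }
  tab$n_cases <- as.integer(table(adr)[tab$adr_term])
  tab$n_death <- cnt(f_death)
  tab$n_serious <- cnt(f_serious)
  tab$n_disability <- cnt(f_disab)
  tab$n_none <- cnt(f_none)
  tab$n_death_serious <- cnt(ds_case)
  tab$p_death <- tab$n_death / tab$n_cases
  tab$p_serious <- tab$n_serious / tab$n_cases
  tab$p_disability <- tab$n_disability / tab$n_cases
  tab$p_none <- tab$n_none / tab$n_cases
  tab <- tab[, c("adr_term", "n_cases", "n_death", "p_death", "n_serious",
                 "p_serious", "n_disability", "p_disability", "n_none",
                 "p_none", "n_death_serious")]
  if (min_reports > 0) {
    dropped <- sum(tab$n_cases < min_reports)
    if (dropped > 0L) {
      saedr_log("%d ADR(s) below min_reports=%d excluded", dropped, min_reports)
    }
    tab <- tab[tab$n_cases >= min_reports, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(list(table = tab, n_cases = n,
                 n_cases_death_serious = sum(ds_case)),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("<outcome_table> %d ADRs over %d cases (%d with death/serious outcome)\n",
              nrow(x$table), x$n_cases, x$n_cases_death_serious))
  invisible(x)
}

#' Write an outcome table to TSV
#' @param outcomes an `outcome_table`.
#' @param path output path.
#' @export
write_outcome_table <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "outcome_table"))
  write.table(outcomes$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
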