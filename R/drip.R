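#' Read a SIDER-style label frequency table
#'
#' TSV with columns `drug_id`, `adr_pt`, `freq_point`, `freq_min`,
#' `freq_max`; blank/NA frequency fields mean the label reports the ADR
#' without frequency information.
#'
#' @param path TSV path.
#' @return data.frame of label frequency records with a derived `freq_kind`
#'   column (`point`, `range` or `missing`).
#' @export
read_label_frequencies <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("drug_id", "adr_pt", "freq_point", "freq_min", "freq_max")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    saedr_stop("frequency table missing column(s): %s", paste(miss, collapse = ", "))
  }
  for (col in c("freq_point", "freq_min", "freq_max")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$freq_kind <- frequency_kind(df)
  validate_frequency_records(df)
  df
}

# internal: classify each record as point / range / missing
frequency_kind <- function(df) {
  ifelse(!is.na(df$freq_point), "point",
         ifelse(!is.na(df$freq_min) & !is.na(df$freq_max), "range", "missing"))
}

validate_frequency_records <- function(df) {
  fp <- df$freq_point[df$freq_kind == "point"]
  if (any(fp < 0 | fp > 1)) saedr_stop("point frequency outside [0,1]")
  rg <- df$freq_kind == "range"
  if (any(df$freq_min[rg] > df$freq_max[rg] | df$freq_min[rg] < 0 |
            df$freq_max[rg] > 1)) {
    saedr_stop("invalid frequency range (need 0 <= min <= max <= 1)")
  }
  invisible(df)
}

#' Sample ADR frequencies for one label record
#'
#' Point records return the reported frequency on every draw; range records
#' draw uniformly between the minimum and maximum reported frequencies;
#' records with no frequency information draw uniformly on
#' \[0.001, 0.01\] (the rare-event prior used for unquantified label ADRs).
#'
#' @param rec a single-row label frequency record (needs `freq_point`,
#'   `freq_min`, `freq_max`; `freq_kind` derived if absent).
#' @param n number of draws (default 1).
#' @return numeric vector of `n` frequencies in \[0,1\].
#' @export
sample_frequency <- function(rec, n = 1) {
  if (is.null(rec$freq_kind)) rec$freq_kind <- frequency_kind(rec)
  validate_frequency_records(as.data.frame(rec))
  switch(rec$freq_kind,
         point = rep(rec$freq_point, n),
         range = runif(n, rec$freq_min, rec$freq_max),
         missing = runif(n, MISSING_FREQ_LOWER, MISSING_FREQ_UPPER))
}

# frequency bounds of the rare-event prior for unquantified label ADRs
MISSING_FREQ_LOWER <- 0.001
MISSING_FREQ_UPPER <- 0.01

#' DRIP score for one drug
#'
#' Each of `n_samples` joint draws samples a frequency for every ADR on the
#' drug's label (independently per ADR) and computes
#' sum over label ADRs of severity(ADR) x frequency(ADR); the DRIP score is
#' the mean over draws, with 5%/95% quantiles as spread.  Label ADRs without
#' a severity score are skipped and counted.
#'
#' @param records the drug's label frequency records (data.frame rows).
#' @param severities a `severity_table`, or a data.frame with columns
#'   `pt_id` and a severity column.
#' @param n_samples joint frequency draws (default 1000).
#' @param rng_seed integer seed.
#' @param severity_col severity column to use (default `"score_normalized"`).
#' @return one-row data.frame: drug_id, drip_mean, drip_q05, drip_q95,
#'   n_adrs_scored, n_adrs_skipped — or, when no label ADR has a severity,
#'   an `NA` score row (logged).
#' @export
drip_score <- function(records, severities, n_samples = 1000, rng_seed = 1L,
                       severity_col = "score_normalized") {
  sev <- severity_lookup(severities, severity_col)
  drug <- if (nrow(records) > 0L) records$drug_id[1L] else NA_character_
  if (nrow(records) > 0L && length(unique(records$drug_id)) > 1L) {
    saedr_stop("drip_score expects records for a single drug")
  }
  if (is.null(records$freq_kind)) records$freq_kind <- frequency_kind(records)
  validate_frequency_records(records)
  m <- match(records$adr_pt, names(sev))
  skipped <- sum(is.na(m))
  if (skipped > 0L) {
    saedr_log("drug %s: skipping %d label ADR(s) without severity score",
              drug, skipped)
  }
  rec <- records[!is.na(m), , drop = FALSE]
  sv <- unname(sev[m[!is.na(m)]])
  if (nrow(rec) == 0L) {
    return(data.frame(drug_id = drug, drip_mean = NA_real_, drip_q05 = NA_real_,
                      drip_q95 = NA_real_, n_adrs_scored = 0L,
                      n_adrs_skipped = skipped, stringsAsFactors = FALSE))
  }
  set.seed(rng_seed)
  totals <- numeric(n_samples)
  draws <- matrix(NA_real_, n_samples, nrow(rec))
  for (j in seq_len(nrow(rec))) {
    draws[, j] <- sample_frequency(rec[j, ], n_samples)
  }
  totals <- as.numeric(draws %*% sv)
  q <- quantile(totals, c(0.05, 0.95), names = FALSE)
  data.frame(drug_id = drug, drip_mean = mean(totals), drip_q05 = q[1L],
             drip_q95 = q[2L], n_adrs_scored = nrow(rec),
             n_adrs_skipped = skipped, stringsAsFactors = FALSE)
}

# internal: severity table / data.frame -> named numeric vector by pt_id
severity_lookup <- function(severities, severity_col = "score_normalized") {
  if (inherits(severities, "severity_table")) severities <- severities$pt
  stopifnot(is.data.frame(severities), "pt_id" %in% names(severities),
            severity_col %in% names(severities))
  setNames(severities[[severity_col]], severities$pt_id)
}

#' DRIP scores for every drug in a label frequency table
#'
#' Applies [drip_score()] per drug with a drug-specific RNG substream
#' derived from `rng_seed`, so the table is reproducible and independent of
#' drug order.
#'
#' @inheritParams drip_score
#' @param freq_table label frequency records for many drugs.
#' @return A `drip_table`: data.frame of per-drug rows (see [drip_score()]),
#'   ordered by drug_id.
#' @export
drip_table <- function(freq_table, severities, n_samples = 1000, rng_seed = 1L,
                       severity_col = "score_normalized") {
  if (is.null(freq_table$freq_kind)) freq_table$freq_kind <- frequency_kind(freq_table)
  drugs <- sort(unique(freq_table$drug_id))
  rows <- lapply(seq_along(drugs), function(i) {
    sub <- freq_table[freq_table$drug_id == drugs[i], , drop = FALSE]
    seed_i <- as.integer((as.numeric(rng_seed) * 1009 +
                            sum(utf8ToInt(drugs[i]))) %% 2147483647)
    drip_score(sub, severities, n_samples, seed_i, severity_col)
  })
  out <- do.call(rbind, rows)
  out$n_samples <- as.integer(n_samples)
  class(out) <- c("drip_table", class(out))
  out
}

#' Per-group DRIP score summaries
#'
#' Groups drugs by a user-supplied mapping (e.g. ATC classes) and reports
#' median and quartiles of DRIP scores per group; drugs absent from the
#' grouping are summarized separately under `"<ungrouped>"`.
#'
#' @param drip a `drip_table` (or data.frame with drug_id, drip_mean).
#' @param grouping data.frame with columns `drug_id` and `group`.
#' @return data.frame: group, n_drugs, q25, median, q75.
#' @export
group_drip <- function(drip, grouping) {
  stopifnot(all(c("drug_id", "group") %in% names(grouping)))
  d <- drip[!is.na(drip$drip_mean), , drop = FALSE]
  if (!any(d$drug_id %in% grouping$drug_id)) {
    saedr_stop("grouping covers no scored drug")
  }
  g <- grouping$group[match(d$drug_id, grouping$drug_id)]
  g[is.na(g)] <- "<ungrouped>"
  parts <- split(d$drip_mean, g)
  out <- data.frame(group = names(parts),
                    n_drugs = vapply(parts, length, 0L),
                    q25 = vapply(parts, function(v) quantile(v, 0.25, names = FALSE), 0),
                    median = vapply(parts, median, 0),
                    q75 = vapply(parts, function(v) quantile(v, 0.75, names = FALSE), 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}
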