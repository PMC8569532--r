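#' Indel similarity (edit ratio) between two strings
#'
#' The classic Levenshtein "ratio": `(|a| + |b| - D(a, b)) / (|a| + |b|)`,
#' where `D` is the generalized edit distance with insertion/deletion cost 1
#' and substitution cost 2 (a substitution counts as delete + insert, so `D`
#' is the indel distance).  Near-duplicate medical terms ("cardiac arrest" vs
#' "cardiac arrest acute") score close to 1; unrelated terms score low.
#' Two empty strings have similarity 1 by convention.
#'
#' @param a,b character vectors (recycled to common length).
#' @return numeric vector of similarities in \[0, 1\].
#' @examples
#' indel_similarity("death", "death")           # 1
#' indel_similarity("a", "b")                   # 0
#' indel_similarity("cardiac arrest", "cardiac arrest acute")
#' @export
indel_similarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  tot <- nchar(a) + nchar(b)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- adist(a[i], b[i],
                  costs = list(insertions = 1, deletions = 1, substitutions = 2))
  }
  out <- ifelse(tot == 0, 1, (tot - d) / pmax(tot, 1))
  as.numeric(out)
}

#' Ranked term list constructor
#'
#' A total ordering of ADR terms, most-extreme first, with optional aligned
#' scores.  Duplicated terms are rejected.
#'
#' @param terms character vector, most-extreme first.
#' @param scores optional numeric vector aligned with `terms`.
#' @return A `ranked_terms` object (list with `terms`, `scores`).
#' @export
ranked_terms <- function(terms, scores = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) saedr_stop("duplicate terms in ranking")
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(terms))
    scores <- as.numeric(scores)
  }
  structure(list(terms = terms, scores = scores), class = "ranked_terms")
}

#' @export
print.ranked_terms <- function(x, ...) {
  cat(sprintf("<ranked_terms> %d terms%s\n", length(x$terms),
              if (is.null(x$scores)) "" else " (scored)"))
  invisible(x)
}

#' Filter a ranked list down to lexically distinct terms
#'
#' Greedy scan in rank order: a term is kept iff its indel similarity to
#' every previously kept term is at most `threshold`.  This removes
#' terminology near-duplicates ("cardiac arrest" after "cardiac arrest
#' acute") that would otherwise let a single concept dominate the seed set.
#' The output preserves rank order and is a subsequence of the input.
#'
#' @param ranked a `ranked_terms` (or character vector, most-extreme first).
#' @param threshold similarity above which a term is dropped (default 0.5).
#' @return a `ranked_terms` with the kept subsequence (scores subset along).
#' @export
filter_lexically_distinct <- function(ranked, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.character(ranked)) ranked <- ranked_terms(ranked)
  stopifnot(inherits(ranked, "ranked_terms"))
  terms <- ranked$terms
  kept <- logical(length(terms))
  kept_terms <- character(0)
  for (i in seq_along(terms)) {
    if (length(kept_terms) == 0L ||
        all(indel_similarity(terms[i], kept_terms) <= threshold)) {
      kept[i] <- TRUE
      kept_terms <- c(kept_terms, terms[i])
    }
  }
  ranked_terms(terms[kept], if (is.null(ranked$scores)) NULL else ranked$scores[kept])
}

#' Rank ADRs by their association with death-or-serious case outcomes
#'
#' For each ADR the statistic is the number of death-or-serious-outcome cases
#' that report the ADR divided by the number of death-or-serious-outcome
#' cases that do not (the ADR's marginal weight among bad outcomes).  With
#' `proportions = TRUE` both counts are divided by the respective case-group
#' sizes (cases with / without the ADR), giving a risk ratio instead.  A zero
#' denominator yields `Inf` and ranks first (logged).
#'
#' @param outcomes an `outcome_table` from [outcome_proportions()].
#' @param proportions use proportions instead of raw counts (default FALSE,
#'   raw counts).
#' @return list with `severe` and `benign`: `ranked_terms` sorted descending
#'   and ascending by the statistic (score attached).  Ties broken by term.
#' @export
rank_from_outcomes <- function(outcomes, proportions = FALSE) {
  stopifnot(inherits(outcomes, "outcome_table"))
  tab <- outcomes$table
  total_ds <- outcomes$n_cases_death_serious
  with_ds <- tab$n_death_serious
  without_ds <- total_ds - with_ds
  if (proportions) {
    n_total <- outcomes$n_cases
    num <- ifelse(tab$n_cases > 0, with_ds / tab$n_cases, 0)
    den_n <- n_total - tab$n_cases
    den <- ifelse(den_n > 0, without_ds / den_n, 0)
  } else {
    num <- with_ds
    den <- without_ds
  }
  stat <- ifelse(den == 0 & num > 0, Inf, ifelse(den == 0, 0, num / den))
  if (any(is.infinite(stat))) {
    saedr_log("%d ADR(s) with zero-denominator outcome statistic ranked most severe",
              sum(is.infinite(stat)))
  }
  o_sev <- order(-stat, tab$adr_term)
  o_ben <- order(stat, tab$adr_term)
  list(severe = ranked_terms(tab$adr_term[o_sev], stat[o_sev]),
       benign = ranked_terms(tab$adr_term[o_ben], stat[o_ben]))
}

#' Build equal-length severe and benign seed sets
#'
#' Takes the top `pct`% of each ranked list (severe list ranked most-severe
#' first, benign list most-benign first), restricts to terms present as
#' network nodes, removes lexical near-duplicates with
#' [filter_lexically_distinct()], and truncates both lists to the shorter
#' length so the two walk ensembles are balanced.
#'
#' @param severe_ranked,benign_ranked `ranked_terms` (or character vectors),
#'   most-extreme first, drawn from the same severity source.
#' @param pct percentage of each ranked list to take, in (0, 50).
#' @param network_nodes character vector of network node terms (optional;
#'   seeds absent from it are dropped and logged).
#' @param threshold lexical-distinctness threshold (default 0.5).
#' @param source_id label recorded on the result.
#' @return A `seed_sets` object: list with `severe`, `benign` (equal-length
#'   disjoint character vectors), `source_id`, `pct`.
#' @export
make_seed_sets <- function(severe_ranked, benign_ranked, pct,
                           network_nodes = NULL, threshold = 0.5,
                           source_id = "ranking") {
  stopifnot(pct > 0, pct < 50)
  if (is.character(severe_ranked)) severe_ranked <- ranked_terms(severe_ranked)
  if (is.character(benign_ranked)) benign_ranked <- ranked_terms(benign_ranked)

  take <- function(r) {
    n <- max(1L, floor(length(r$terms) * pct / 100))
    terms <- head(r$terms, n)
    if (!is.null(network_nodes)) {
      drop <- sum(!terms %in% network_nodes)
      if (drop > 0L) {
        saedr_log("dropping %d seed term(s) absent from the network", drop)
      }
      terms <- terms[terms %in% network_nodes]
    }
    filter_lexically_distinct(ranked_terms(terms), threshold)$terms
  }
  sev <- take(severe_ranked)
  ben <- take(benign_ranked)
  if (length(sev) == 0L || length(ben) == 0L) {
    saedr_stop("empty seed list after filtering (severe: %d, benign: %d)",
               length(sev), length(ben))
  }
  m <- min(length(sev), length(ben))
  sev <- sev[seq_len(m)]; ben <- ben[seq_len(m)]
  clash <- intersect(sev, ben)
  if (length(clash) > 0L) {
    saedr_log("removing %d term(s) present in both seed lists", length(clash))
    sev <- setdiff(sev, clash); ben <- setdiff(ben, clash)
    m <- min(length(sev), length(ben))
    if (m == 0L) saedr_stop("seed lists empty after removing overlap")
    sev <- sev[seq_len(m)]; ben <- ben[seq_len(m)]
  }
  structure(list(severe = sev, benign = ben, source_id = source_id, pct = pct),
            class = "seed_sets")
}

#' @export
print.seed_sets <- function(x, ...) {
  cat(sprintf("<seed_sets> %d severe / %d benign seeds (source '%s', pct %.1f)\n",
              length(x$severe), length(x$benign), x$source_id, x$pct))
  invisible(x)
}

#' Write seed sets to TSV (term, polarity, rank, source_id)
#'
#' @param seeds a `seed_sets`.
#' @param path output TSV path.
#' @export
write_seed_sets <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_sets"))
  df <- rbind(
    data.frame(term = seeds$severe, polarity = "severe",
               rank = seq_along(seeds$severe), stringsAsFactors = FALSE),
    data.frame(term = seeds$benign, polarity = "benign",
               rank = seq_along(seeds$benign), stringsAsFactors = FALSE))
  df$source_id <- seeds$source_id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seed_sets
#' @export
read_seed_sets <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  stopifnot(all(c("term", "polarity", "rank") %in% names(df)))
  sev <- df[df$polarity == "severe", ]
  ben <- df[df$polarity == "benign", ]
  structure(list(severe = sev$term[order(sev$rank)],
                 benign = ben$term[order(ben$rank)],
                 source_id = if ("source_id" %in% names(df)) df$source_id[1] else "file",
                 pct = NA_real_),
            class = "seed_sets")
}
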