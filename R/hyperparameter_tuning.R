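#' Hyperparameter tuning grid
#'
#' Defaults follow the published grid: neighbor counts
#' \{2, 5, 10, 15, 20, 25, 30\} crossed with seed percentages
#' \{2, 5, 10, 15, 20, 25\}, with a 75% training split.
#'
#' @param k_values integer set of neighbor counts.
#' @param pct_values numeric set of seed percentages.
#' @param split_fraction training fraction in (0,1).
#' @return a `tuning_grid` list.
#' @export
tuning_grid <- function(k_values = c(2, 5, 10, 15, 20, 25, 30),
                        pct_values = c(2, 5, 10, 15, 20, 25),
                        split_fraction = 0.75) {
  stopifnot(length(k_values) >= 1, length(pct_values) >= 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(k_values = sort(unique(as.integer(k_values))),
                 pct_values = sort(unique(as.numeric(pct_values))),
                 split_fraction = split_fraction),
            class = "tuning_grid")
}

#' Randomly split a ranking into training and test sets
#'
#' Terms unmappable to the network are dropped first (and counted); the
#' remainder is randomly partitioned.  Both halves keep their original
#' relative rank order and scores.
#'
#' @param ranking a `ranked_terms`.
#' @param fraction training fraction in (0,1).
#' @param rng_seed integer seed.
#' @param network_nodes optional character vector; terms absent from it are
#'   dropped before splitting.
#' @return list with `train`, `test` (`ranked_terms`) and `n_dropped`.
#' @export
split_ranking <- function(ranking, fraction, rng_seed = 1L, network_nodes = NULL) {
  stopifnot(inherits(ranking, "ranked_terms"), fraction > 0, fraction < 1)
  terms <- ranking$terms
  scores <- ranking$scores
  keep <- rep(TRUE, length(terms))
  if (!is.null(network_nodes)) keep <- terms %in% network_nodes
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    saedr_log("dropped %d term(s) unmappable to the network before splitting", n_dropped)
  }
  terms <- terms[keep]
  if (!is.null(scores)) scores <- scores[keep]
  n <- length(terms)
  set.seed(rng_seed)
  n_train <- round(fraction * n)
  idx <- sort(sample.int(n, n_train))
  mk <- function(i) ranked_terms(terms[i], if (is.null(scores)) NULL else scores[i])
  list(train = mk(idx), test = mk(setdiff(seq_len(n), idx)), n_dropped = n_dropped)
}

#' Spearman rank correlation with tie handling
#'
#' Average-rank ties; two-sided p-value from the t approximation (exact
#' p-values are unavailable under ties).  Constant input yields `NA` rho
#' with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' One-sided two-sample comparison of score groups
#'
#' Welch t-test of the hypothesis that group `a` has greater mean than group
#' `b`; group medians reported alongside.  If both groups are constant the
#' test is degenerate: `p` is 0.5 when the constants are equal, otherwise 0
#' or 1 according to the direction (documented convention).
#'
#' @param scores_a,scores_b numeric vectors (each length >= 2).
#' @param direction only `"a_greater"` supported.
#' @return list with `t_stat`, `p`, `medians` (named pair), `n` (pair).
#' @export
compare_groups <- function(scores_a, scores_b, direction = "a_greater") {
  stopifnot(identical(direction, "a_greater"))
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    saedr_stop("compare_groups needs >= 2 observations per group")
  }
  meds <- c(a = median(scores_a), b = median(scores_b))
  res <- tryCatch(
    stats::t.test(scores_a, scores_b, alternative = "greater"),
    error = function(e) NULL)
  if (is.null(res)) {
    # degenerate: zero variance in both groups
    d <- mean(scores_a) - mean(scores_b)
    return(list(t_stat = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 0.5 else if (d > 0) 0 else 1,
                medians = meds,
                n = c(a = length(scores_a), b = length(scores_b))))
  }
  list(t_stat = unname(res$statistic), p = res$p.value, medians = meds,
       n = c(a = length(scores_a), b = length(scores_b)))
}

# internal: deterministic, enumeration-order-free RNG substream per grid cell
cell_seed <- function(rng_seed, k, pct) {
  v <- (as.numeric(rng_seed) * 1000003 + as.numeric(k) * 10007 +
          round(as.numeric(pct) * 100) * 97) %% 2147483647
  as.integer(v)
}

#' Grid search over neighbor count and seed percentage
#'
#' For every (k, pct) pair: build the k-NN network, derive severe/benign
#' seeds from the extremes of the training ranking, propagate severity by
#' random walks, and compute the Spearman correlation between the resulting
#' per-term scores and the training scores over scored training terms.
#' Returns the full table and the argmax configuration; correlation ties are
#' broken by smaller k then smaller pct (prefer the sparser model).
#' Infeasible cells (e.g. empty post-filter seed lists) are recorded as
#' failed and excluded from the argmax.  Each cell runs on an independent
#' RNG substream derived from (rng_seed, k, pct), so results do not depend
#' on enumeration order.
#'
#' @param lexicon a `lexicon`.
#' @param train a `ranked_terms` with scores (higher = more severe).
#' @param grid a [tuning_grid()].
#' @param cfg a [walk_config()] used for every cell (its `rng_seed` seeds the
#'   per-cell substreams).
#' @param n_boot bootstrap iterations per cell (0 = use point scores;
#'   default 0 for tractable tuning).
#' @return A `tuning_result`: list with `table` (k, pct, rho, p, n_terms,
#'   status) and `best_config` (k, pct, rho).
#' @export
grid_search <- function(lexicon, train, grid = tuning_grid(), cfg = walk_config(),
                        n_boot = 0) {
  stopifnot(inherits(lexicon, "lexicon"), inherits(train, "ranked_terms"),
            inherits(grid, "tuning_grid"))
  if (length(train$terms) == 0L) saedr_stop("empty training ranking")
  if (is.null(train$scores)) saedr_stop("training ranking must carry scores")

  cells <- expand.grid(k = grid$k_values, pct = grid$pct_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- cells$k[i]; pct <- cells$pct[i]
    rows[[i]] <- tryCatch({
      net <- build_knn_network(lexicon, k)
      # most-severe-first and most-benign-first views of the training ranking
      o <- order(-train$scores)
      sev_rank <- ranked_terms(train$terms[o], train$scores[o])
      ben_rank <- ranked_terms(rev(train$terms[o]), rev(train$scores[o]))
      seeds <- make_seed_sets(sev_rank, ben_rank, pct,
                              network_nodes = net$nodes$term,
                              source_id = "train")
      cell_cfg <- walk_config(cfg$n_walks_per_seed, cfg$walk_length,
                              cell_seed(cfg$rng_seed, k, pct))
      tally <- run_walks(net, seeds, cell_cfg)
      sc <- if (n_boot > 0) {
        bootstrap_scores(tally, n_boot, rng_seed = cell_seed(cfg$rng_seed, k, pct))
      } else point_scores(tally)
      col <- if (n_boot > 0) "boot_mean" else "score"
      m <- match(train$terms, sc$term)
      ok <- !is.na(m) & !is.na(sc[[col]][m])
      if (sum(ok) < 3L) stop("fewer than 3 scored training terms")
      rc <- rank_correlation(sc[[col]][m[ok]], train$scores[ok])
      data.frame(k = k, pct = pct, rho = rc$rho, p = rc$p,
                 n_terms = sum(ok), status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      saedr_log("grid cell (k=%d, pct=%g) failed: %s", k, pct, conditionMessage(e))
      data.frame(k = k, pct = pct, rho = NA_real_, p = NA_real_,
                 n_terms = 0L, status = "failed", stringsAsFactors = FALSE)
    })
  }
  tab <- do.call(rbind, rows)
  ok <- tab[tab$status == "ok" & !is.na(tab$rho), , drop = FALSE]
  if (nrow(ok) == 0L) saedr_stop("every grid configuration failed")
  ok <- ok[order(-ok$rho, ok$k, ok$pct), , drop = FALSE]
  best <- ok[1L, ]
  structure(list(table = tab,
                 best_config = list(k = best$k, pct = best$pct, rho = best$rho)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d cells; best k = %d, pct = %g (rho = %.3f)\n",
              nrow(x$table), x$best_config$k, x$best_config$pct,
              x$best_config$rho))
  invisible(x)
}
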