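#' Random-walk configuration
#'
#' @param n_walks_per_seed walks started from each seed node (default 5000).
#' @param walk_length steps per walk (default 200).  The start position is
#'   not counted as a visit; each of the `walk_length` subsequent positions
#'   is, including repeats.
#' @param rng_seed integer seed recorded in all downstream outputs.
#' @return a `walk_config` list.
#' @export
walk_config <- function(n_walks_per_seed = 5000, walk_length = 200, rng_seed = 1L) {
  stopifnot(n_walks_per_seed >= 1, walk_length >= 1)
  structure(list(n_walks_per_seed = as.integer(n_walks_per_seed),
                 walk_length = as.integer(walk_length),
                 rng_seed = as.integer(rng_seed)),
            class = "walk_config")
}

# internal: simulate `n_per_start` first-order weighted walks of `len` steps
# from each start index; returns a sparse visit matrix (walks x nodes) and
# the start index of every walk.  Transitions are drawn proportional to
# incident edge weight.  Chunked over walks to bound memory.
simulate_walks <- function(adj, starts, n_per_start, len, chunk_walks = 20000L) {
  n <- length(adj$terms)
  W <- length(starts) * n_per_start
  if (W == 0L) {
    return(list(visits = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              x = numeric(0), dims = c(0L, n)),
                start = integer(0)))
  }
  start_of_walk <- rep(starts, each = n_per_start)
  mats <- list()
  done <- 0L
  while (done < W) {
    m <- min(chunk_walks, W - done)
    cur <- start_of_walk[done + seq_len(m)]
    ii <- integer(0); jj <- integer(0)
    for (step in seq_len(len)) {
      groups <- split(seq_len(m), cur)
      nxt <- integer(m)
      for (u_chr in names(groups)) {
        u <- as.integer(u_chr)
        idx <- groups[[u_chr]]
        cw <- adj$cw[[u]]
        nb <- adj$nbr[[u]]
        r <- runif(length(idx)) * cw[length(cw)]
        nxt[idx] <- nb[findInterval(r, cw) + 1L]
      }
      cur <- nxt
      ii <- c(ii, seq_len(m)); jj <- c(jj, cur)
    }
    mats[[length(mats) + 1L]] <- Matrix::sparseMatrix(
      i = ii, j = jj, x = 1, dims = c(m, n))
    done <- done + m
  }
  visits <- if (length(mats) == 1L) mats[[1L]] else do.call(rbind, mats)
  list(visits = visits, start = start_of_walk)
}

#' Run weighted random walks from severe and benign seed nodes
#'
#' From every seed node, `cfg$n_walks_per_seed` first-order weighted random
#' walks of `cfg$walk_length` steps are simulated; at each step the next node
#' is drawn with probability proportional to incident edge weight.  Every
#' position after the start is tallied to the polarity (severe/benign) of the
#' walk's seed.  Nodes outside the component(s) containing seeds are flagged
#' unreachable; nodes never visited are reported.
#'
#' The returned tally retains per-walk visit counts (sparse matrices) so that
#' [bootstrap_scores()] can resample whole walks.
#'
#' @param network a `lexical_network`.
#' @param seeds a `seed_sets`; every seed must be a network node with at
#'   least one edge.
#' @param cfg a [walk_config()].
#' @return A `walk_tally`: list with `terms`, `s`, `b` (per-node visit count
#'   vectors, self-visits included; exclusion happens at scoring),
#'   `visits_severe`/`visits_benign` (sparse walk-by-node matrices),
#'   `start_severe`/`start_benign` (seed index of each walk), `seeds`, `cfg`,
#'   `unreachable` (logical), `unvisited` (logical).
#' @export
run_walks <- function(network, seeds, cfg = walk_config()) {
  stopifnot(inherits(network, "lexical_network"), inherits(seeds, "seed_sets"),
            inherits(cfg, "walk_config"))
  adj <- network_adjacency(network)
  miss <- setdiff(c(seeds$severe, seeds$benign), adj$terms)
  if (length(miss) > 0L) {
    saedr_stop("seed term(s) not in network: %s", paste(head(miss, 5L), collapse = ", "))
  }
  isev <- match(seeds$severe, adj$terms)
  iben <- match(seeds$benign, adj$terms)
  deg0 <- c(isev, iben)[lengths(adj$nbr[c(isev, iben)]) == 0L]
  if (length(deg0) > 0L) {
    saedr_stop("seed node with no edges: %s", adj$terms[deg0[1L]])
  }

  set.seed(cfg$rng_seed)
  sev <- simulate_walks(adj, isev, cfg$n_walks_per_seed, cfg$walk_length)
  ben <- simulate_walks(adj, iben, cfg$n_walks_per_seed, cfg$walk_length)

  reach <- reachable_from(adj, c(isev, iben))
  s <- as.numeric(Matrix::colSums(sev$visits))
  b <- as.numeric(Matrix::colSums(ben$visits))
  unvisited <- (s + b) == 0
  if (any(!reach)) {
    saedr_log("%d node(s) unreachable from any seed component", sum(!reach))
  }
  if (any(unvisited & reach)) {
    saedr_log("%d reachable node(s) unvisited; consider more walks per seed",
              sum(unvisited & reach))
  }
  structure(list(terms = adj$terms, s = s, b = b,
                 visits_severe = sev$visits, visits_benign = ben$visits,
                 start_severe = sev$start, start_benign = ben$start,
                 seeds = seeds, cfg = cfg,
                 unreachable = !reach, unvisited = unvisited),
            class = "walk_tally")
}

#' @export
print.walk_tally <- function(x, ...) {
  cat(sprintf("<walk_tally> %d nodes; %d severe + %d benign walks; %d unvisited\n",
              length(x$terms), nrow(x$visits_severe), nrow(x$visits_benign),
              sum(x$unvisited)))
  invisible(x)
}

#' Exchange the severe/benign polarity of a walk tally
#'
#' Used for the label-swap antisymmetry property: scores computed from the
#' swapped tally equal one minus the original scores, exactly.
#'
#' @param tally a `walk_tally`.
#' @return a `walk_tally` with polarities exchanged.
#' @export
swap_polarity <- function(tally) {
  stopifnot(inherits(tally, "walk_tally"))
  out <- tally
  out$s <- tally$b; out$b <- tally$s
  out$visits_severe <- tally$visits_benign
  out$visits_benign <- tally$visits_severe
  out$start_severe <- tally$start_benign
  out$start_benign <- tally$start_severe
  out$seeds <- structure(list(severe = tally$seeds$benign,
                              benign = tally$seeds$severe,
                              source_id = tally$seeds$source_id,
                              pct = tally$seeds$pct), class = "seed_sets")
  out
}

#' Raw severity score from visit counts
#'
#' The visit-ratio score `s_u / (s_u + b_u)`: the fraction of all walk visits
#' to a node that came from severe-seeded walks.  1 means only severe walks
#' reach the node, 0 only benign walks, 0.5 perfect balance.
#'
#' @param s_u,b_u nonnegative visit counts (vectorized).
#' @return score in \[0,1\]; `NA` where `s_u + b_u == 0` (undefined).
#' @export
saedr_raw <- function(s_u, b_u) {
  stopifnot(all(s_u >= 0, na.rm = TRUE), all(b_u >= 0, na.rm = TRUE))
  tot <- s_u + b_u
  ifelse(tot > 0, s_u / tot, NA_real_)
}

# internal: per-walk visit matrices with seed self-visits zeroed.
# Visits to a seed node u made during walks that started at u are excluded
# from u's own tally (self_visits = "exclude_own_walks"); "include" disables
# the exclusion.
excluded_visit_matrices <- function(tally, self_visits = c("exclude_own_walks", "include")) {
  self_visits <- match.arg(self_visits)
  Ms <- tally$visits_severe
  Mb <- tally$visits_benign
  if (self_visits == "exclude_own_walks") {
    seed_idx <- unique(c(tally$start_severe, tally$start_benign))
    for (u in seed_idx) {
      rs <- which(tally$start_severe == u)
      if (length(rs) > 0L) Ms[rs, u] <- 0
      rb <- which(tally$start_benign == u)
      if (length(rb) > 0L) Mb[rb, u] <- 0
    }
    Ms <- Matrix::drop0(Ms); Mb <- Matrix::drop0(Mb)
  }
  list(severe = Ms, benign = Mb)
}

#' Point severity scores from a walk tally
#'
#' Applies seed self-visit exclusion, then scores every node with
#' [saedr_raw()].  Unvisited nodes get `NA`.
#'
#' @param tally a `walk_tally`.
#' @param self_visits `"exclude_own_walks"` (default: visits to a seed during
#'   walks it started are excluded from its own tally) or `"include"`.
#' @return data.frame: term, s, b, score.
#' @export
point_scores <- function(tally, self_visits = "exclude_own_walks") {
  M <- excluded_visit_matrices(tally, self_visits)
  s <- as.numeric(Matrix::colSums(M$severe))
  b <- as.numeric(Matrix::colSums(M$benign))
  data.frame(term = tally$terms, s = s, b = b, score = saedr_raw(s, b),
             stringsAsFactors = FALSE)
}

#' Bootstrap-averaged severity scores
#'
#' Each iteration resamples whole walks with replacement, independently
#' within the severe and benign walk sets (each keeping its size), recomputes
#' the visit-ratio score per node, and the final score is the mean over the
#' iterations in which the node was visited.  The spread is reported as a
#' normal-approximation interval (mean +/- 1.96 bootstrap sd).
#'
#' @param tally a `walk_tally` (per-walk visit records retained).
#' @param n_boot bootstrap iterations (default 10000).
#' @param rng_seed integer seed for the resampling.
#' @param self_visits see [point_scores()].
#' @return data.frame: term, s, b, score (point), boot_mean, boot_lo,
#'   boot_hi, n_contrib (iterations contributing an estimate).
#' @export
bootstrap_scores <- function(tally, n_boot = 10000, rng_seed = 1L,
                             self_visits = "exclude_own_walks") {
  stopifnot(inherits(tally, "walk_tally"), n_boot >= 1)
  M <- excluded_visit_matrices(tally, self_visits)
  Ws <- nrow(M$severe); Wb <- nrow(M$benign)
  n <- length(tally$terms)
  tMs <- Matrix::t(M$severe); tMb <- Matrix::t(M$benign)

  set.seed(rng_seed)
  sum_sc <- numeric(n); sum_sq <- numeric(n); n_contrib <- integer(n)
  for (it in seq_len(n_boot)) {
    ws <- tabulate(sample.int(Ws, Ws, replace = TRUE), nbins = Ws)
    wb <- tabulate(sample.int(Wb, Wb, replace = TRUE), nbins = Wb)
    s <- as.numeric(tMs %*% ws)
    b <- as.numeric(tMb %*% wb)
    tot <- s + b
    hit <- tot > 0
    sc <- s[hit] / tot[hit]
    sum_sc[hit] <- sum_sc[hit] + sc
    sum_sq[hit] <- sum_sq[hit] + sc^2
    n_contrib[hit] <- n_contrib[hit] + 1L
  }
  mean_sc <- ifelse(n_contrib > 0, sum_sc / n_contrib, NA_real_)
  var_sc <- ifelse(n_contrib > 1,
                   pmax(0, sum_sq / n_contrib - mean_sc^2) * n_contrib / (n_contrib - 1),
                   0)
  sd_sc <- sqrt(var_sc)
  pt <- point_scores(tally, self_visits)
  data.frame(term = pt$term, s = pt$s, b = pt$b, score = pt$score,
             boot_mean = mean_sc,
             boot_lo = pmax(0, mean_sc - 1.96 * sd_sc),
             boot_hi = pmin(1, mean_sc + 1.96 * sd_sc),
             n_contrib = n_contrib, stringsAsFactors = FALSE)
}

#' Aggregate per-term scores to preferred-term level and normalize
#'
#' Within each seed-set run, a preferred term's (PT) score is the mean of its
#' member terms' scores; across runs, the PT score is the mean of the
#' per-run PT scores (over the runs in which the PT was scored).  The
#' combined column is then min-max normalized to \[0,1\] — applied once,
#' after cross-run averaging.  PTs with no scored terms are absent (logged).
#'
#' @param per_term_scores a data.frame (or list of data.frames, one per
#'   seed-set run) with columns `term` and a score column.
#' @param lexicon a `lexicon` providing the term -> pt_id mapping.
#' @param score_col which column to aggregate (default `"boot_mean"` if
#'   present, else `"score"`).
#' @return A `severity_table`: list with `pt` (data.frame: pt_id, terms,
#'   score_pre, score_normalized), `per_term` (stacked per-run term scores),
#'   `n_runs`.
#' @export
aggregate_and_normalize <- function(per_term_scores, lexicon,
                                    score_col = NULL) {
  if (is.data.frame(per_term_scores)) per_term_scores <- list(per_term_scores)
  stopifnot(length(per_term_scores) >= 1, inherits(lexicon, "lexicon"))

  per_run_pt <- lapply(seq_along(per_term_scores), function(r) {
    df <- per_term_scores[[r]]
    col <- score_col
    if (is.null(col)) col <- if ("boot_mean" %in% names(df)) "boot_mean" else "score"
    stopifnot("term" %in% names(df), col %in% names(df))
    df <- df[!is.na(df[[col]]), , drop = FALSE]
    df$pt_id <- lexicon_pt(lexicon, df$term)
    if (anyNA(df$pt_id)) {
      saedr_stop("scored term without pt_id in lexicon: %s",
                 df$term[which(is.na(df$pt_id))[1L]])
    }
    agg <- aggregate(df[[col]], by = list(pt_id = df$pt_id), FUN = mean)
    names(agg)[2L] <- "score"
    agg$run <- r
    agg
  })
  all_pt <- do.call(rbind, per_run_pt)
  if (nrow(all_pt) == 0L) saedr_stop("no scored terms to aggregate")
  combined <- aggregate(all_pt$score, by = list(pt_id = all_pt$pt_id), FUN = mean)
  names(combined)[2L] <- "score_pre"

  all_pts <- unique(lexicon$records$pt_id)
  dropped <- setdiff(all_pts, combined$pt_id)
  if (length(dropped) > 0L) {
    saedr_log("%d PT(s) with no scored terms absent from severity table",
              length(dropped))
  }
  rng <- range(combined$score_pre)
  if (rng[2L] > rng[1L]) {
    combined$score_normalized <- (combined$score_pre - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    combined$score_normalized <- rep(0.5, nrow(combined))
    saedr_log("degenerate score range; normalized column set to 0.5")
  }
  terms_by_pt <- split(lexicon$records$term, lexicon$records$pt_id)
  combined$terms <- vapply(terms_by_pt[combined$pt_id],
                           paste, "", collapse = "|")
  combined <- combined[order(combined$pt_id),
                       c("pt_id", "terms", "score_pre", "score_normalized")]
  rownames(combined) <- NULL
  structure(list(pt = combined, per_term = all_pt,
                 n_runs = length(per_term_scores)),
            class = "severity_table")
}

#' @export
print.severity_table <- function(x, ...) {
  cat(sprintf("<severity_table> %d PTs from %d seed-set run(s); normalized range [%.3f, %.3f]\n",
              nrow(x$pt), x$n_runs, min(x$pt$score_normalized),
              max(x$pt$score_normalized)))
  invisible(x)
}

#' Write a severity table to TSV
#'
#' Columns: pt_id, terms, score_pre, score_normalized.
#' @param severity a `severity_table`.
#' @param path output path.
#' @export
write_severity_table <- function(severity, path) {
  stopifnot(inherits(severity, "severity_table"))
  write.table(severity$pt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
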