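# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: similarity via an LCS dynamic program, k-NN via
# naive all-pairs scans, walk expectations via transition-matrix powers,
# bootstrap expectations via exhaustive resample enumeration.

# indel similarity via longest common subsequence:
# D_indel = |a| + |b| - 2*LCS, ratio = 2*LCS / (|a| + |b|)
oracle_indel_similarity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n + m == 0) return(1)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1, j + 1] <- if (x[i] == y[j]) L[i, j] + 1L
                         else max(L[i, j + 1], L[i + 1, j])
    }
  }
  2 * L[n + 1, m + 1] / (n + m)
}

# brute-force union-kNN edge list over a named vector matrix.
# Ties in similarity broken by lexicographic term order (matching the
# documented determinism rule).
oracle_knn_edges <- function(V, k, eps = 1e-8) {
  V <- V[order(rownames(V)), , drop = FALSE]
  n <- nrow(V)
  U <- V / sqrt(rowSums(V^2))
  S <- tcrossprod(U)
  edges <- list()
  for (i in seq_len(n)) {
    s <- S[i, ]; s[i] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    for (j in nb) {
      a <- min(i, j); b <- max(i, j)
      edges[[paste(a, b)]] <- c(a, b)
    }
  }
  m <- do.call(rbind, edges)
  w <- pmax(pmin(S[m], 1), eps)
  df <- data.frame(a = rownames(V)[m[, 1]], b = rownames(V)[m[, 2]],
                   weight = w, stringsAsFactors = FALSE)
  df[order(df$a, df$b), ]
}

# row-stochastic transition matrix of a lexical_network
oracle_transition_matrix <- function(network) {
  terms <- network$nodes$term
  n <- length(terms)
  A <- matrix(0, n, n, dimnames = list(terms, terms))
  for (r in seq_len(nrow(network$edges))) {
    a <- network$edges$a[r]; b <- network$edges$b[r]; w <- network$edges$weight[r]
    A[a, b] <- A[a, b] + w
    A[b, a] <- A[b, a] + w
  }
  A / rowSums(A)
}

# expected visits per node for one L-step walk from `start`:
# sum_{t=1..L} (P^t)[start, ]
oracle_expected_visits <- function(P, start, L) {
  p <- numeric(nrow(P)); names(p) <- rownames(P)
  p[start] <- 1
  v <- numeric(nrow(P)); names(v) <- rownames(P)
  for (t in seq_len(L)) {
    p <- as.numeric(p %*% P); names(p) <- rownames(P)
    v <- v + p
  }
  v
}

# exhaustive bootstrap expectation for tiny walk sets: enumerates every
# ordered with-replacement resample of the severe and benign walk index
# sets and averages the per-node score over outcomes where defined.
oracle_bootstrap_mean <- function(Vs, Vb) {
  Ws <- nrow(Vs); Wb <- nrow(Vb); n <- ncol(Vs)
  res_s <- expand.grid(rep(list(seq_len(Ws)), Ws))
  res_b <- expand.grid(rep(list(seq_len(Wb)), Wb))
  sum_sc <- numeric(n); n_contrib <- numeric(n)
  for (i in seq_len(nrow(res_s))) {
    s <- colSums(Vs[unlist(res_s[i, ]), , drop = FALSE])
    for (j in seq_len(nrow(res_b))) {
      b <- colSums(Vb[unlist(res_b[j, ]), , drop = FALSE])
      tot <- s + b
      hit <- tot > 0
      sum_sc[hit] <- sum_sc[hit] + s[hit] / tot[hit]
      n_contrib[hit] <- n_contrib[hit] + 1
    }
  }
  ifelse(n_contrib > 0, sum_sc / n_contrib, NA_real_)
}

# brute-force per-ADR outcome tabulation from a case_set (list-of-lists walk)
oracle_outcome_table <- function(cases) {
  map1 <- function(code) {
    if (code == "Death") "Death"
    else if (code %in% c("Life-Threatening", "Hospitalization",
                         "Other Serious", "Required Intervention")) "Serious Outcome"
    else if (code %in% c("Congenital Anomaly", "Disability")) "Disability"
    else "Unmapped"
  }
  adrs <- sort(unique(unlist(cases$reactions)))
  out <- data.frame(adr_term = adrs, n_cases = 0L, n_death = 0L,
                    n_serious = 0L, n_disability = 0L, n_none = 0L,
                    n_death_serious = 0L, stringsAsFactors = FALSE)
  rownames(out) <- adrs
  for (i in seq_len(nrow(cases))) {
    ocs <- cases$outcomes[[i]]
    cats <- if (length(ocs) == 0) "No Outcome"
            else setdiff(unique(vapply(ocs, map1, "")), "Unmapped")
    for (a in unique(cases$reactions[[i]])) {
      out[a, "n_cases"] <- out[a, "n_cases"] + 1L
      if ("Death" %in% cats) out[a, "n_death"] <- out[a, "n_death"] + 1L
      if ("Serious Outcome" %in% cats) out[a, "n_serious"] <- out[a, "n_serious"] + 1L
      if ("Disability" %in% cats) out[a, "n_disability"] <- out[a, "n_disability"] + 1L
      if ("No Outcome" %in% cats) out[a, "n_none"] <- out[a, "n_none"] + 1L
      if (any(c("Death", "Serious Outcome") %in% cats)) {
        out[a, "n_death_serious"] <- out[a, "n_death_serious"] + 1L
      }
    }
  }
  rownames(out) <- NULL
  out
}

# permutation-test oracle for the one-sided two-sample comparison
oracle_permutation_p <- function(a, b, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (mean(pool[idx]) - mean(pool[-idx]) >= obs) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# hand-rolled Spearman rho: Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
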