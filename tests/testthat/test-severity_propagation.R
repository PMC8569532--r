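# two-node path network fixture: a -- b with weight 1
path_network <- function() {
  V <- rbind(a = c(1, 0), b = c(1, 0))
  build_knn_network(lexicon_from_matrix(V), 1)
}

test_that("a forced walk on the two-node path gives the deterministic tally", {
  net <- path_network()
  seeds <- raw_seed_sets(severe = "a", benign = character(0))
  tally <- run_walks(net, seeds, walk_config(1, 3, 99))
  # a -> b -> a -> b: start not counted, so s_b = 2, s_a = 1
  expect_equal(setNames(tally$s, tally$terms), c(a = 1, b = 2))
  expect_equal(tally$b, c(0, 0))
  # a's self-visit is excluded at scoring because a is a (severe) seed
  sc <- point_scores(tally)
  expect_equal(sc$s[sc$term == "a"], 0)
  expect_equal(sc$s[sc$term == "b"], 2)
})

test_that("seeds missing from the network or without edges are hard errors", {
  net <- path_network()
  expect_error(run_walks(net, raw_seed_sets("zz", "b"), walk_config(1, 2, 1)),
               "not in network")
})

test_that("empirical visits match the Markov matrix-power oracle on a triangle", {
  V <- rbind(x = c(1, 0.0), y = c(0.92, 0.4), z = c(0.6, 0.8))
  net <- build_knn_network(lexicon_from_matrix(V), 2)
  P <- oracle_transition_matrix(net)
  L <- 50; n_walks <- 2000
  tally <- run_walks(net, raw_seed_sets("x", "z"), walk_config(n_walks, L, 7))

  exp_s <- oracle_expected_visits(P, "x", L)
  per_walk <- as.matrix(tally$visits_severe)
  for (node in tally$terms) {
    j <- match(node, tally$terms)
    se <- stats::sd(per_walk[, j]) / sqrt(n_walks)
    expect_lt(abs(mean(per_walk[, j]) - exp_s[node]), 3 * max(se, 1e-9))
  }
})

test_that("under-sampled walks report unvisited nodes", {
  set.seed(41)
  V <- matrix(rnorm(30 * 4), 30, 4)
  rownames(V) <- paste0("v", sprintf("%02d", 1:30))
  net <- build_knn_network(lexicon_from_matrix(V), 2)
  expect_message(
    tally <- run_walks(net, raw_seed_sets("v01", "v02"), walk_config(1, 1, 3)),
    "unvisited")
  expect_gt(sum(tally$unvisited), 0)
})

test_that("saedr_raw implements s/(s+b) with boundary and NA behaviour", {
  expect_equal(saedr_raw(100, 100), 0.5)
  expect_equal(saedr_raw(0, 7), 0)
  expect_equal(saedr_raw(7, 0), 1)
  expect_equal(saedr_raw(3, 1), 0.75)
  expect_true(is.na(saedr_raw(0, 0)))
  # monotonicity: increasing b at fixed s strictly decreases the score
  s <- 5
  vals <- saedr_raw(rep(s, 10), 1:10)
  expect_true(all(diff(vals) < 0))
})

test_that("label swap maps every pre-normalization score to 1 - score, exactly", {
  set.seed(42)
  V <- matrix(rnorm(20 * 4), 20, 4)
  rownames(V) <- paste0("u", sprintf("%02d", 1:20))
  net <- build_knn_network(lexicon_from_matrix(V), 3)
  tally <- run_walks(net, raw_seed_sets(c("u01", "u02"), c("u19", "u20")),
                     walk_config(50, 10, 13))
  a <- point_scores(tally)
  b <- point_scores(swap_polarity(tally))
  # the swap exchanges the integer tallies exactly ...
  expect_identical(a$s, b$b)
  expect_identical(a$b, b$s)
  # ... so score' = b/(s+b) = 1 - score, up to one float rounding
  ok <- !is.na(a$score)
  expect_identical(ok, !is.na(b$score))
  expect_true(all(abs(a$score[ok] + b$score[ok] - 1) <= 4 * .Machine$double.eps))
})

test_that("bootstrap degenerates correctly with identical or single walks", {
  terms <- c("p", "q", "r")
  # all severe walks identical, all benign walks identical
  Vs <- matrix(rep(c(2, 1, 0), each = 4), 4, 3)
  Vb <- matrix(rep(c(0, 1, 2), each = 4), 4, 3)
  # start nodes sit on zero columns of their own matrices, so seed
  # self-exclusion is a no-op here
  tally <- tally_from_matrices(terms, Vs, Vb, rep(3L, 4), rep(1L, 4))
  bs <- bootstrap_scores(tally, n_boot = 50, rng_seed = 2)
  expect_equal(bs$boot_mean, bs$score)
  expect_equal(bs$boot_hi - bs$boot_lo, rep(0, 3))

  # one walk per polarity: every resample reproduces the originals
  t1 <- tally_from_matrices(terms, Vs[1, , drop = FALSE], Vb[1, , drop = FALSE],
                            3L, 1L)
  b1 <- bootstrap_scores(t1, n_boot = 20, rng_seed = 3)
  expect_equal(b1$boot_mean, b1$score)
})

test_that("bootstrap mean matches the exhaustive-enumeration oracle", {
  terms <- c("w1", "w2", "w3", "w4")
  set.seed(43)
  Vs <- matrix(rpois(8, 2), 2, 4)   # 2 severe walks
  Vb <- matrix(rpois(8, 2), 2, 4)   # 2 benign walks
  # start nodes chosen outside the tallied columns so no self-exclusion applies
  tally <- tally_from_matrices(terms, Vs, Vb, c(1L, 1L), c(4L, 4L))
  tally$visits_severe[, 1] <- 0; tally$visits_benign[, 4] <- 0
  Vs2 <- as.matrix(tally$visits_severe); Vb2 <- as.matrix(tally$visits_benign)

  truth <- oracle_bootstrap_mean(Vs2, Vb2)
  n_boot <- 2000
  bs <- bootstrap_scores(tally, n_boot = n_boot, rng_seed = 5)
  # per-iteration score sd -> standard error of the bootstrap mean
  for (j in which(!is.na(truth))) {
    # enumerate per-outcome scores for the sd
    scores <- c()
    for (i1 in 1:2) for (i2 in 1:2) for (j1 in 1:2) for (j2 in 1:2) {
      s <- Vs2[i1, j] + Vs2[i2, j]; b <- Vb2[j1, j] + Vb2[j2, j]
      if (s + b > 0) scores <- c(scores, s / (s + b))
    }
    se <- stats::sd(scores) / sqrt(n_boot)
    expect_lt(abs(bs$boot_mean[j] - truth[j]), 3 * max(se, 1e-9))
  }
})

test_that("PT aggregation and min-max normalization follow the stated rules", {
  tt <- data.frame(term = c("t1", "t2", "t3", "t4"),
                   tokens = c("t1", "t2", "t3", "t4"),
                   pt_id = c("P1", "P2", "P3", "P3"), stringsAsFactors = FALSE)
  sp <- load_embeddings(write_embedding_fixture(
    paste(tt$term, "1 0")))
  lex <- build_lexicon(tt, sp)

  # single run, single-term PTs: min-max on two points
  r1 <- data.frame(term = c("t1", "t2"), score = c(0.2, 0.6))
  sv <- aggregate_and_normalize(r1, lex)
  expect_equal(setNames(sv$pt$score_normalized, sv$pt$pt_id),
               c(P1 = 0, P2 = 1))

  # two identical runs equal either run pre-normalization
  sv2 <- aggregate_and_normalize(list(r1, r1), lex)
  expect_equal(sv2$pt$score_pre, sv$pt$score_pre)

  # multi-term PT: run 1 {0.4, 0.8} -> 0.6; run 2 {0.6} -> 0.6; combined 0.6
  rA <- data.frame(term = c("t3", "t4", "t1"), score = c(0.4, 0.8, 0.1))
  rB <- data.frame(term = c("t3", "t1"), score = c(0.6, 0.3))
  sv3 <- aggregate_and_normalize(list(rA, rB), lex)
  expect_equal(sv3$pt$score_pre[sv3$pt$pt_id == "P3"], 0.6)

  # final combined column spans exactly [0, 1]
  expect_equal(min(sv3$pt$score_normalized), 0)
  expect_equal(max(sv3$pt$score_normalized), 1)
})

test_that("NA-scored terms drop out and missing PTs are logged", {
  tt <- data.frame(term = c("t1", "t2"), tokens = c("t1", "t2"),
                   pt_id = c("P1", "P2"), stringsAsFactors = FALSE)
  lex <- build_lexicon(tt, load_embeddings(write_embedding_fixture(
    c("t1 1 0", "t2 0 1"))))
  r <- data.frame(term = c("t1", "t2"), score = c(0.4, NA))
  expect_message(sv <- aggregate_and_normalize(r, lex), "no scored terms")
  expect_equal(sv$pt$pt_id, "P1")
})
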