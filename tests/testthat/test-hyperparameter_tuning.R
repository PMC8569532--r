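test_that("split_ranking partitions deterministically and counts drops", {
  rk <- ranked_terms(paste0("t", 1:100), 100:1)
  sp <- split_ranking(rk, 0.75, rng_seed = 5)
  expect_length(sp$train$terms, 75)
  expect_length(sp$test$terms, 25)
  expect_length(intersect(sp$train$terms, sp$test$terms), 0)
  expect_setequal(c(sp$train$terms, sp$test$terms), rk$terms)

  sp2 <- split_ranking(rk, 0.75, rng_seed = 5)
  expect_identical(sp, sp2)

  nodes <- paste0("t", 5:100)   # 4 unmappable terms
  expect_message(sp3 <- split_ranking(rk, 0.5, 1, nodes), "dropped 4")
  expect_equal(sp3$n_dropped, 4)
  expect_false(any(c("t1", "t4") %in% c(sp3$train$terms, sp3$test$terms)))
})

test_that("rank_correlation matches hand computation and handles ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, rev(x))$rho, -1)

  # 6 points with a tie: rho equals rank-transform + Pearson on ranks
  a <- c(10, 20, 20, 30, 40, 50)
  b <- c(3, 1, 4, 2, 6, 5)
  expect_equal(rank_correlation(a, b)$rho, oracle_spearman(a, b))

  expect_warning(rc <- rank_correlation(rep(1, 5), x), "constant")
  expect_true(is.na(rc$rho))
})

test_that("rank_correlation is invariant under strictly monotone transforms", {
  set.seed(71)
  x <- rnorm(30); y <- rnorm(30)
  base <- rank_correlation(x, y)$rho
  expect_equal(rank_correlation(exp(x), y)$rho, base)
  expect_equal(rank_correlation(x, y^3 + 5 * y)$rho, base)
})

test_that("compare_groups performs a one-sided test with medians", {
  x <- c(1, 2, 3, 4)
  same <- compare_groups(x, x)
  expect_equal(same$p, 0.5)
  expect_equal(unname(same$t_stat), 0)
  expect_equal(unname(same$medians), c(2.5, 2.5))

  set.seed(72)
  a <- rnorm(50, 1); b <- rnorm(50, 0)
  res <- compare_groups(a, b)
  expect_lt(res$p, 0.001)
  # permutation oracle agrees on order of magnitude of significance
  expect_lt(oracle_permutation_p(a, b), 0.005)

  # degenerate variance convention
  deg <- compare_groups(c(0, 0), c(1, 1))
  expect_equal(deg$p, 1)
  expect_error(compare_groups(1, c(1, 2)), ">= 2")
})

# small planted instance reused by the grid tests
tuning_fixture <- function() {
  space <- gen_embedding_space(n_terms = 40, dim = 6, noise_sd = 0.2,
                               rng_seed = 77, phrase_fraction = 0)
  lex <- build_lexicon(space$term_table,
                       load_embeddings(write_planted_space(space, tempfile())[["embeddings"]]))
  o <- order(-space$latent)
  train <- ranked_terms(names(space$latent)[o], unname(space$latent)[o])
  list(lex = lex, train = train)
}

test_that("grid_search enumerates the exact Cartesian product", {
  fx <- tuning_fixture()
  grid <- tuning_grid(k_values = c(2, 3), pct_values = c(10, 20))
  res <- suppressMessages(grid_search(fx$lex, fx$train, grid,
                                      walk_config(30, 10, 3)))
  got <- res$table[order(res$table$k, res$table$pct), c("k", "pct")]
  want <- expand.grid(k = c(2, 3), pct = c(10, 20), KEEP.OUT.ATTRS = FALSE)
  want <- want[order(want$k, want$pct), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))

  # default grid is the published Cartesian product, including (25,10) and (10,10)
  dg <- tuning_grid()
  cells <- expand.grid(k = dg$k_values, pct = dg$pct_values)
  expect_equal(nrow(cells), 7 * 6)
  expect_true(any(cells$k == 25 & cells$pct == 10))
  expect_true(any(cells$k == 10 & cells$pct == 10))
})

test_that("grid_search argmax equals exhaustive re-evaluation, any order", {
  fx <- tuning_fixture()
  cfg <- walk_config(50, 15, 9)
  grid <- tuning_grid(k_values = c(2, 4), pct_values = c(15, 25))
  res <- suppressMessages(grid_search(fx$lex, fx$train, grid, cfg))

  # exhaustive recomputation of every cell through the public stage functions
  recompute <- function(k, pct) {
    net <- build_knn_network(fx$lex, k)
    o <- order(-fx$train$scores)
    sev <- ranked_terms(fx$train$terms[o], fx$train$scores[o])
    ben <- ranked_terms(rev(sev$terms), rev(sev$scores))
    seeds <- make_seed_sets(sev, ben, pct, network_nodes = net$nodes$term)
    tally <- run_walks(net, seeds,
                       walk_config(cfg$n_walks_per_seed, cfg$walk_length,
                                   saedr:::cell_seed(cfg$rng_seed, k, pct)))
    sc <- point_scores(tally)
    m <- match(fx$train$terms, sc$term)
    ok <- !is.na(m) & !is.na(sc$score[m])
    rank_correlation(sc$score[m[ok]], fx$train$scores[ok])$rho
  }
  cells <- expand.grid(k = c(2, 4), pct = c(15, 25))
  rhos <- suppressMessages(mapply(recompute, cells$k, cells$pct))
  for (i in seq_len(nrow(cells))) {
    row <- res$table[res$table$k == cells$k[i] & res$table$pct == cells$pct[i], ]
    expect_equal(row$rho, rhos[i])
  }
  best_i <- order(-rhos, cells$k, cells$pct)[1]
  expect_equal(res$best_config$k, cells$k[best_i])
  expect_equal(res$best_config$pct, cells$pct[best_i])

  # enumeration-order invariance of the argmax
  grid_rev <- tuning_grid(k_values = c(4, 2), pct_values = c(25, 15))
  res_rev <- suppressMessages(grid_search(fx$lex, fx$train, grid_rev, cfg))
  expect_equal(res_rev$best_config, res$best_config)
})

test_that("a 1x1 grid returns its single configuration; failures are recorded", {
  fx <- tuning_fixture()
  res <- suppressMessages(grid_search(fx$lex, fx$train,
                                      tuning_grid(k_values = 3, pct_values = 20),
                                      walk_config(30, 10, 2)))
  expect_equal(nrow(res$table), 1)
  expect_equal(res$best_config$k, 3)

  # infeasible cell (k too large for the node count) recorded, not fatal
  res2 <- suppressMessages(grid_search(
    fx$lex, fx$train, tuning_grid(k_values = c(3, 500), pct_values = 20),
    walk_config(30, 10, 2)))
  expect_equal(res2$table$status, c("ok", "failed"))
  expect_equal(res2$best_config$k, 3)
})
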