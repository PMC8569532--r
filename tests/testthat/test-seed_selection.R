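test_that("indel_similarity matches its definition and the DP oracle", {
  expect_equal(indel_similarity("death", "death"), 1.0)
  expect_equal(indel_similarity("a", "b"), 0.0)
  expect_equal(indel_similarity("", ""), 1.0)

  s <- indel_similarity("cardiac arrest", "cardiac arrest acute")
  expect_equal(s, oracle_indel_similarity("cardiac arrest", "cardiac arrest acute"))
  expect_gt(s, 0.5)

  set.seed(31)
  for (i in 1:25) {
    a <- paste(sample(c(letters[1:6], " "), sample(0:12, 1), TRUE), collapse = "")
    b <- paste(sample(c(letters[1:6], " "), sample(0:12, 1), TRUE), collapse = "")
    expect_equal(indel_similarity(a, b), oracle_indel_similarity(a, b),
                 info = paste(a, "~", b))
  }
})

test_that("lexical filter reproduces the worked seed-list example", {
  sev <- filter_lexically_distinct(c("death", "cardiac arrest acute", "cardiac arrest"))
  expect_equal(sev$terms, c("death", "cardiac arrest acute"))
  ben <- filter_lexically_distinct(c("dry skin", "yawning", "cold sweat"))
  expect_equal(ben$terms, c("dry skin", "yawning", "cold sweat"))
})

test_that("lexical filter removes exact duplicates and passes distinct lists", {
  r <- ranked_terms(c("fatigue", "nausea"), c(2, 1))
  expect_equal(filter_lexically_distinct(r)$terms, c("fatigue", "nausea"))

  # exact duplicate of a kept term is dropped (similarity 1 > threshold);
  # ranked_terms itself refuses duplicates, so go through character input path
  via_df <- filter_lexically_distinct(
    ranked_terms(c("rash", "rash y", "itching")), threshold = 0.5)
  expect_equal(via_df$terms, c("rash", "itching"))
})

test_that("filter output is a subsequence with all kept pairs below threshold", {
  set.seed(32)
  for (rep in 1:10) {
    terms <- unique(replicate(20, paste(sample(letters, sample(4:12, 1), TRUE),
                                        collapse = "")))
    out <- filter_lexically_distinct(ranked_terms(terms), 0.5)$terms
    expect_true(all(out %in% terms))
    expect_equal(out, terms[terms %in% out])   # subsequence, order preserved
    if (length(out) > 1) {
      prs <- combn(out, 2)
      sims <- mapply(oracle_indel_similarity, prs[1, ], prs[2, ])
      expect_true(all(sims <= 0.5))
    }
  }
})

test_that("rank_from_outcomes follows the counts-ratio definition", {
  # ADR A: 5 death-or-serious cases with A, 50 without A -> 0.1
  recs <- c(
    lapply(1:5, function(i) list(case_id = paste0("A", i), is_duplicate = FALSE,
                                 country = "US", reactions = c("adr a"),
                                 outcomes = "Death")),
    lapply(1:50, function(i) list(case_id = paste0("B", i), is_duplicate = FALSE,
                                  country = "US", reactions = c("adr b"),
                                  outcomes = "Hospitalization")),
    # ADR C never in a death-or-serious case -> 0, most benign
    lapply(1:4, function(i) list(case_id = paste0("C", i), is_duplicate = FALSE,
                                 country = "US", reactions = c("adr c"),
                                 outcomes = character(0))))
  cases <- suppressMessages(normalize_cases(as_case_set(recs)))
  ot <- outcome_proportions(cases)
  rk <- rank_from_outcomes(ot)
  stat <- setNames(rk$severe$scores, rk$severe$terms)
  expect_equal(unname(stat["adr a"]), 5 / 50)
  expect_equal(unname(stat["adr c"]), 0)
  expect_equal(rk$benign$terms[1], "adr c")
})

test_that("outcome ranking equals brute-force enumeration on a 3-ADR table", {
  set.seed(33)
  adrs <- c("aa", "bb", "cc")
  recs <- lapply(1:40, function(i) {
    list(case_id = sprintf("K%03d", i), is_duplicate = FALSE, country = "US",
         reactions = sample(adrs, sample(1:2, 1)),
         outcomes = if (runif(1) < 0.4) sample(c("Death", "Other Serious"), 1)
                    else character(0))
  })
  cases <- suppressMessages(normalize_cases(as_case_set(recs)))
  rk <- rank_from_outcomes(outcome_proportions(cases))
  o <- oracle_outcome_table(cases)
  tot_ds <- sum(vapply(seq_len(nrow(cases)), function(i) {
    ocs <- cases$outcomes[[i]]
    length(ocs) > 0 && any(ocs %in% c("Death", "Life-Threatening",
                                      "Hospitalization", "Other Serious",
                                      "Required Intervention"))
  }, TRUE))
  expected <- o$n_death_serious / (tot_ds - o$n_death_serious)
  expect_equal(setNames(rk$severe$scores, rk$severe$terms)[o$adr_term],
               setNames(expected, o$adr_term))
})

test_that("make_seed_sets truncates, drops non-network seeds, stays disjoint", {
  # 8-term rankings; pct = 45 takes the top 3 of each
  sev <- c("death", "cardiac arrest acute", "cardiac arrest",
           "sepsis", "stroke", "coma", "renal failure", "seizure")
  ben <- c("dry skin", "yawning", "cold sweat",
           "sneezing", "hiccups", "thirst", "chapped lips", "bruise")
  nodes <- c(sev, ben)

  # severe top-3 filters to 2 near-duplicate-free terms; benign top-3 stays 3;
  # truncation to the shorter length reproduces the worked example exactly
  ss <- make_seed_sets(sev, ben, 45, network_nodes = nodes)
  expect_equal(ss$severe, c("death", "cardiac arrest acute"))
  expect_equal(ss$benign, c("dry skin", "yawning"))
  expect_length(intersect(ss$severe, ss$benign), 0)

  # distinct lists pass through intact (top-3 on both sides, no duplicates)
  ss0 <- make_seed_sets(sev[-3], ben, 45, network_nodes = nodes)
  expect_equal(ss0$severe, c("death", "cardiac arrest acute", "sepsis"))
  expect_equal(ss0$benign, c("dry skin", "yawning", "cold sweat"))

  # a seed absent from the network is dropped before filtering
  expect_message(
    ss2 <- make_seed_sets(sev, ben, 45, network_nodes = setdiff(nodes, "death")),
    "absent from the network")
  expect_false("death" %in% ss2$severe)

  # empty post-filter list is a hard error
  expect_error(make_seed_sets(sev, ben, 45, network_nodes = "yawning"),
               "empty seed list")
})

test_that("seed-set equal-length/disjoint invariants hold on random input", {
  set.seed(34)
  for (rep in 1:5) {
    terms <- unique(replicate(40, paste(sample(letters, sample(5:10, 1), TRUE),
                                        collapse = "")))
    sc <- runif(length(terms))
    rk <- ranked_terms(terms[order(-sc)], sort(sc, decreasing = TRUE))
    bk <- ranked_terms(rev(rk$terms), rev(rk$scores))
    ss <- make_seed_sets(rk, bk, 25, network_nodes = terms)
    expect_equal(length(ss$severe), length(ss$benign))
    expect_length(intersect(ss$severe, ss$benign), 0)
  }
})

test_that("seed sets round-trip through TSV", {
  ss <- raw_seed_sets(c("death", "sepsis"), c("yawning", "sneezing"))
  f <- tempfile()
  write_seed_sets(ss, f)
  back <- read_seed_sets(f)
  expect_equal(back$severe, ss$severe)
  expect_equal(back$benign, ss$benign)
})
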