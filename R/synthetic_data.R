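#' Generate an embedding space with a planted latent severity axis
#'
#' Emulates the structure the severity-propagation method assumes: each term
#' has a latent severity drawn uniform on \[0,1\], and its embedding is
#' `latent * direction + noise` for a fixed random unit direction and
#' isotropic Gaussian noise.  `noise_sd` parameterizes the expected total
#' noise norm relative to the unit-length severity axis (per-coordinate sd is
#' `noise_sd / sqrt(dim)`), so the signal-to-noise ratio does not depend on
#' `dim`.  A configurable number of lexical near-duplicate "clone" terms is
#' added: a clone is a suffix-edited string variant of its parent, shares the
#' parent's latent severity and PT, and gets a fresh noise draw — these
#' exercise the seed-list lexical filter and PT-level aggregation.
#'
#' Term strings are random lowercase words (so unrelated terms are lexically
#' distinct); a fraction of terms are two-token phrases whose tokens each
#' carry the term vector, exercising phrase averaging.
#'
#' @param n_terms number of base terms (>= 10).
#' @param dim embedding dimensionality (>= 2).
#' @param noise_sd total-norm noise scale (default 0.3).
#' @param n_clones number of near-duplicate clone terms (default 0).
#' @param rng_seed integer seed; all outputs are pure functions of the
#'   arguments and this seed.
#' @param phrase_fraction fraction of base terms rendered as two-token
#'   phrases (default 0.2).
#' @return A `planted_space`: list with `term_table` (data.frame: term,
#'   tokens, pt_id), `embeddings` (token-level matrix, rownames = tokens),
#'   `latent` (named per-term severities), `direction`, `noise_sd`,
#'   `clone_map` (data.frame: clone, parent), `rng_seed`.
#' @export
gen_embedding_space <- function(n_terms = 500, dim = 32, noise_sd = 0.3,
                                n_clones = 0, rng_seed = 1L,
                                phrase_fraction = 0.2) {
  stopifnot(n_terms >= 10, dim >= 2, noise_sd >= 0, n_clones >= 0)
  set.seed(rng_seed)

  words <- random_words(n_terms + n_clones + ceiling(n_terms * phrase_fraction) + 10L)
  base_terms <- words[seq_len(n_terms)]
  extra <- words[-seq_len(n_terms)]

  latent <- runif(n_terms)
  names(latent) <- base_terms
  direction <- rnorm(dim)
  direction <- direction / sqrt(sum(direction^2))
  coord_sd <- noise_sd / sqrt(dim)

  term_vec <- function(l) l * direction + rnorm(dim, 0, coord_sd)
  vecs <- t(vapply(latent, term_vec, numeric(dim)))

  # phrases: replace some single-token terms by two-token renderings; both
  # tokens carry the term vector so the token mean reproduces it exactly
  n_phrase <- floor(n_terms * phrase_fraction)
  phrase_idx <- if (n_phrase > 0) sort(sample.int(n_terms, n_phrase)) else integer(0)
  tokens <- as.list(base_terms)
  tok_rows <- list()
  for (i in seq_len(n_terms)) {
    if (i %in% phrase_idx) {
      t2 <- extra[length(tok_rows) + 1L]
      tokens[[i]] <- c(base_terms[i], t2)
      tok_rows[[length(tok_rows) + 1L]] <- t2
    }
  }
  token_names <- c(base_terms, unlist(tok_rows))
  token_vecs <- rbind(vecs,
                      if (length(tok_rows) > 0) vecs[phrase_idx, , drop = FALSE])
  rownames(token_vecs) <- token_names
  term_strings <- vapply(tokens, paste, "", collapse = " ")

  # clones: suffix-edited near-duplicates sharing the parent latent and PT
  clone_map <- data.frame(clone = character(0), parent = character(0),
                          stringsAsFactors = FALSE)
  clone_latent <- numeric(0)
  if (n_clones > 0) {
    parents <- sample.int(n_terms, n_clones, replace = TRUE)
    suffixes <- c(" nos", " acute", " aggravated", "s", " unspecified")
    clone_terms <- character(n_clones)
    for (j in seq_len(n_clones)) {
      clone_terms[j] <- paste0(term_strings[parents[j]],
                               suffixes[1L + (j - 1L) %% length(suffixes)])
    }
    keep <- !clone_terms %in% term_strings & !duplicated(clone_terms)
    parents <- parents[keep]; clone_terms <- clone_terms[keep]
    clone_map <- data.frame(clone = clone_terms,
                            parent = term_strings[parents],
                            stringsAsFactors = FALSE)
    clone_latent <- latent[parents]
    names(clone_latent) <- clone_terms
    cvecs <- t(vapply(clone_latent, term_vec, numeric(dim)))
    ctok <- gsub(" ", "_", clone_terms)  # clone is a single fresh token
    rownames(cvecs) <- ctok
    token_vecs <- rbind(token_vecs, cvecs)
    tokens <- c(tokens, as.list(ctok))
  }

  all_terms <- c(term_strings, clone_map$clone)
  pt_of_base <- sprintf("PT%05d", seq_len(n_terms))
  names(pt_of_base) <- term_strings
  pt_id <- c(pt_of_base,
             unname(pt_of_base[clone_map$parent]))
  term_table <- data.frame(
    term = all_terms,
    tokens = vapply(tokens, paste, "", collapse = "|"),
    pt_id = pt_id, stringsAsFactors = FALSE)
  rownames(term_table) <- NULL

  names(latent) <- term_strings  # latent keyed by final (possibly phrasal) term
  structure(list(term_table = term_table,
                 embeddings = token_vecs,
                 latent = c(latent, clone_latent),
                 direction = direction, noise_sd = noise_sd,
                 clone_map = clone_map, rng_seed = as.integer(rng_seed)),
            class = "planted_space")
}

#' @export
print.planted_space <- function(x, ...) {
  cat(sprintf("<planted_space> %d terms (%d clones), dim %d, noise_sd %.2f\n",
              nrow(x$term_table), nrow(x$clone_map), ncol(x$embeddings),
              x$noise_sd))
  invisible(x)
}

# internal: pronounceable-ish random lowercase words, unique
random_words <- function(n, min_len = 6L, max_len = 10L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(min_len:max_len, need, replace = TRUE)
    w <- vapply(lens, function(l) {
      paste(sample(letters, l, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Write a planted space to embedding-file + term-table + truth TSVs
#'
#' Emits the three files the pipeline readers consume: a word2vec-style text
#' embedding file, a term table TSV (term, tokens, pt_id) and a ground-truth
#' severity TSV (term, pt_id, latent_severity).
#'
#' @param space a `planted_space`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths.
#' @export
write_planted_space <- function(space, dir) {
  stopifnot(inherits(space, "planted_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- file.path(dir, "embeddings.txt")
  V <- space$embeddings
  hdr <- sprintf("%d %d", nrow(V), ncol(V))
  rows <- paste(rownames(V), apply(V, 1L, function(v)
    paste(formatC(v, format = "g", digits = 10), collapse = " ")))
  writeLines(c(hdr, rows), emb)
  tt <- file.path(dir, "terms.tsv")
  write.table(space$term_table, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- file.path(dir, "truth.tsv")
  truth <- data.frame(term = names(space$latent),
                      pt_id = space$term_table$pt_id[
                        match(names(space$latent), space$term_table$term)],
                      latent_severity = unname(space$latent),
                      stringsAsFactors = FALSE)
  write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  c(embeddings = emb, terms = tt, truth = tr)
}

#' Generate synthetic adverse-event case reports
#'
#' Each case samples 1–5 ADR terms from the planted space; the probability
#' that the case carries a death-or-serious outcome is a logistic function
#' of the case's maximum latent severity:
#' `plogis(outcome_slope * (max_latent - 0.5))`, so `outcome_slope = 0`
#' makes outcomes independent of severity.  Severe cases draw a raw code
#' among Death (30%) and the serious codes; non-severe cases are Disability
#' with probability 0.1, else report no outcome.  A configurable fraction of
#' records are duplicate-flagged or assigned a non-US country to exercise
#' [normalize_cases()].
#'
#' @param space a `planted_space`.
#' @param n_cases number of case records.
#' @param outcome_slope logistic slope on latent severity (default 6).
#' @param rng_seed integer seed.
#' @param duplicate_fraction fraction of duplicate-flagged records (default 0.1).
#' @param foreign_fraction fraction of non-US records (default 0.1).
#' @param path optional path; when given, cases are also written as
#'   JSON-lines.
#' @return a `case_set` (invisibly also written to `path` if given).
#' @export
gen_case_reports <- function(space, n_cases, outcome_slope = 6, rng_seed = 1L,
                             duplicate_fraction = 0.1, foreign_fraction = 0.1,
                             path = NULL) {
  stopifnot(inherits(space, "planted_space"), n_cases >= 1)
  set.seed(rng_seed)
  terms <- names(space$latent)
  serious_codes <- c("Life-Threatening", "Hospitalization", "Other Serious",
                     "Required Intervention")
  recs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    k <- sample.int(5L, 1L)
    rx <- sample(terms, k)
    maxsev <- max(space$latent[rx])
    p_bad <- stats::plogis(outcome_slope * (maxsev - 0.5))
    if (runif(1) < p_bad) {
      out <- if (runif(1) < 0.3) "Death" else sample(serious_codes, 1L)
    } else {
      out <- if (runif(1) < 0.1) "Disability" else character(0)
    }
    recs[[i]] <- list(case_id = sprintf("C%06d", i),
                      is_duplicate = runif(1) < duplicate_fraction,
                      country = if (runif(1) < foreign_fraction)
                        sample(c("GB", "DE", "JP", "CA"), 1L) else "US",
                      reactions = rx,
                      outcomes = out)
  }
  if (!is.null(path)) {
    lines <- vapply(recs, function(r) {
      jsonlite::toJSON(r, auto_unbox = TRUE)
    }, "")
    writeLines(lines, path)
  }
  invisible(as_case_set(recs))
}

#' Generate a synthetic SIDER-style label frequency table
#'
#' Assigns each drug a random subset of 3–15 ADR preferred terms; each
#' record is frequency-missing with probability `missing_fraction`, else
#' split evenly between a point frequency (uniform on \[0.001, 0.3\]) and a
#' min/max range around such a point.
#'
#' @param space a `planted_space`.
#' @param n_drugs number of drugs.
#' @param missing_fraction fraction of records without frequency information
#'   (default 0.3).
#' @param rng_seed integer seed.
#' @param path optional TSV output path.
#' @return data.frame of label frequency records (see
#'   [read_label_frequencies()]).
#' @export
gen_label_frequencies <- function(space, n_drugs, missing_fraction = 0.3,
                                  rng_seed = 1L, path = NULL) {
  stopifnot(inherits(space, "planted_space"), n_drugs >= 1,
            missing_fraction >= 0, missing_fraction <= 1)
  set.seed(rng_seed)
  pts <- unique(space$term_table$pt_id)
  rows <- list()
  for (d in seq_len(n_drugs)) {
    drug <- sprintf("DRUG%04d", d)
    k <- sample(3:15, 1L)
    adrs <- sample(pts, min(k, length(pts)))
    for (a in adrs) {
      kind <- if (runif(1) < missing_fraction) "missing"
              else if (runif(1) < 0.5) "point" else "range"
      fp <- fmin <- fmax <- NA_real_
      if (kind == "point") {
        fp <- runif(1, 0.001, 0.3)
      } else if (kind == "range") {
        c0 <- runif(1, 0.001, 0.3)
        half <- runif(1, 0, 0.5) * c0
        fmin <- max(0, c0 - half); fmax <- min(1, c0 + half)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = drug, adr_pt = a, freq_point = fp, freq_min = fmin,
        freq_max = fmax, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$freq_kind <- frequency_kind(df)
  if (!is.null(path)) {
    out <- df[, c("drug_id", "adr_pt", "freq_point", "freq_min", "freq_max")]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(df)
}
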