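#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value`; `[section]` headers scope the keys that
#' follow as `section.key`.  Blank lines and `#` comments are ignored.
#' Values are returned as strings; numeric coercion happens where the
#' pipeline consumes them.
#'
#' @param path config file path.
#' @return named character vector of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) saedr_stop("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- character(0)
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) saedr_stop("malformed config line: %s", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[key] <- val
  }
  out
}

# internal: config lookup with default and optional numeric coercion
cfg_get <- function(config, key, default = NULL, as = "character") {
  # accept both "section.key" and bare "key"
  v <- config[key]
  if (is.na(v)) {
    bare <- sub("^.*\\.", "", key)
    hit <- which(sub("^.*\\.", "", names(config)) == bare)
    v <- if (length(hit) > 0L) config[hit[1L]] else NA_character_
  }
  if (is.na(v)) {
    if (is.null(default)) return(NULL)
    return(default)
  }
  switch(as, numeric = as.numeric(v), integer = as.integer(v),
         logical = as.logical(v), unname(v))
}

#' Read a ranked severity list from TSV
#'
#' Expects columns `term` and either `score` (higher = more severe) or
#' `rank` (1 = most severe).
#'
#' @param path TSV path.
#' @return a `ranked_terms`, most severe first, with scores attached
#'   (ranks are converted to descending scores).
#' @export
read_ranking <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (!"term" %in% names(df)) saedr_stop("ranking file needs a 'term' column")
  df$term <- tolower(df$term)
  if ("score" %in% names(df)) {
    o <- order(-df$score, df$term)
    ranked_terms(df$term[o], df$score[o])
  } else if ("rank" %in% names(df)) {
    o <- order(df$rank, df$term)
    ranked_terms(df$term[o], -df$rank[o])
  } else {
    saedr_stop("ranking file needs a 'score' or 'rank' column")
  }
}

#' Run the full severity pipeline from a configuration
#'
#' Stage sequence: load embeddings and term table, build the k-NN lexical
#' network, derive seed sets from each configured severity source (a ranked
#' list file and/or outcome-based ranking from case reports), run random
#' walks and bootstrap scoring per source, aggregate to PT level with
#' min-max normalization, and (when a frequency table is configured) compute
#' DRIP scores.  All intermediate artifacts are written to the output
#' directory together with a JSON run manifest (config snapshot, seeds,
#' input digests, per-stage timings and row counts, package version).  On
#' stage failure a `FAILED` marker naming the stage is left in the output
#' directory and the error is re-raised.
#'
#' Recognized config keys (section-qualified or bare): `inputs.embeddings`,
#' `inputs.terms`, `inputs.ranking`, `inputs.cases`, `inputs.frequencies`;
#' `params.k`, `params.pct`, `params.n_walks`, `params.walk_length`,
#' `params.n_boot`, `params.rng_seed`, `params.country_filter`,
#' `params.min_reports`; `output.dir`.
#'
#' @param config path to a config file, or a named character vector from
#'   [read_config()].
#' @param overrides named character vector overriding config keys (CLI wins).
#' @return list with `severity` (a `severity_table`), `drip` (a
#'   `drip_table` or NULL) and `manifest` (list), invisibly.
#' @export
run_pipeline <- function(config, overrides = character(0)) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- read_config(config)
  }
  if (length(overrides) > 0L) config[names(overrides)] <- overrides

  out_dir <- cfg_get(config, "output.dir", "saedr_out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  timings <- list()
  counts <- list()
  manifest_path <- file.path(out_dir, "manifest.json")

  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  result <- tryCatch({
    emb_path <- cfg_get(config, "inputs.embeddings")
    terms_path <- cfg_get(config, "inputs.terms")
    if (is.null(emb_path) || is.null(terms_path)) {
      saedr_stop("config must name inputs.embeddings and inputs.terms")
    }
    k <- cfg_get(config, "params.k", 10, "integer")
    pct <- cfg_get(config, "params.pct", 10, "numeric")
    n_walks <- cfg_get(config, "params.n_walks", 5000, "integer")
    walk_length <- cfg_get(config, "params.walk_length", 200, "integer")
    n_boot <- cfg_get(config, "params.n_boot", 10000, "integer")
    rng_seed <- cfg_get(config, "params.rng_seed", 1, "integer")

    lex <- run_stage("lexicon", {
      space <- load_embeddings(emb_path)
      build_lexicon(terms_path, space)
    })
    counts$terms <- nrow(lex$records)
    counts$terms_with_vectors <- sum(lex$records$has_vector)

    net <- run_stage("network", build_knn_network(lex, k))
    counts$nodes <- nrow(net$nodes); counts$edges <- nrow(net$edges)
    write_network(net, file.path(out_dir, "edges.tsv"),
                  file.path(out_dir, "nodes.tsv"))

    seed_sources <- list()
    ranking_path <- cfg_get(config, "inputs.ranking")
    if (!is.null(ranking_path)) {
      rk <- read_ranking(ranking_path)
      ben <- ranked_terms(rev(rk$terms), rev(rk$scores))
      seed_sources$ranking <- list(severe = rk, benign = ben)
    }
    cases_path <- cfg_get(config, "inputs.cases")
    if (!is.null(cases_path)) {
      cs <- run_stage("cases", {
        raw <- read_case_reports(cases_path)
        normalize_cases(raw, cfg_get(config, "params.country_filter", "US"),
                        lexicon = lex)
      })
      counts$cases <- nrow(cs)
      ot <- outcome_proportions(
        cs, cfg_get(config, "params.min_reports", 0, "integer"))
      write_outcome_table(ot, file.path(out_dir, "outcomes.tsv"))
      rko <- rank_from_outcomes(ot)
      seed_sources$outcomes <- rko
    }
    if (length(seed_sources) == 0L) {
      saedr_stop("no severity source configured (inputs.ranking or inputs.cases)")
    }

    runs <- list()
    for (src in names(seed_sources)) {
      ss <- seed_sources[[src]]
      seeds <- run_stage(paste0("seeds_", src), make_seed_sets(
        ss$severe, ss$benign, pct, network_nodes = net$nodes$term,
        source_id = src))
      counts[[paste0("seeds_", src)]] <- length(seeds$severe)
      write_seed_sets(seeds, file.path(out_dir, paste0("seeds_", src, ".tsv")))
      tally <- run_stage(paste0("walks_", src), run_walks(
        net, seeds, walk_config(n_walks, walk_length, rng_seed)))
      counts[[paste0("unvisited_", src)]] <- sum(tally$unvisited)
      sc <- run_stage(paste0("scores_", src), {
        if (n_boot > 0) bootstrap_scores(tally, n_boot, rng_seed)
        else point_scores(tally)
      })
      sc$pt_id <- lexicon_pt(lex, sc$term)
      out_cols <- intersect(c("pt_id", "term", "score", "boot_mean",
                              "boot_lo", "boot_hi", "s", "b"), names(sc))
      per_term_out <- sc[, out_cols]
      names(per_term_out)[names(per_term_out) == "score"] <- "raw_score"
      names(per_term_out)[names(per_term_out) == "boot_mean"] <- "bootstrap_mean"
      names(per_term_out)[names(per_term_out) == "s"] <- "n_visits_severe"
      names(per_term_out)[names(per_term_out) == "b"] <- "n_visits_benign"
      write.table(per_term_out,
                  file.path(out_dir, paste0("scores_", src, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      runs[[src]] <- sc
    }

    severity <- run_stage("aggregate", aggregate_and_normalize(runs, lex))
    counts$pts_scored <- nrow(severity$pt)
    write_severity_table(severity, file.path(out_dir, "severity.tsv"))

    drip <- NULL
    freq_path <- cfg_get(config, "inputs.frequencies")
    if (!is.null(freq_path)) {
      drip <- run_stage("drip", {
        ft <- read_label_frequencies(freq_path)
        drip_table(ft, severity, n_samples = cfg_get(config, "params.n_samples",
                                                     1000, "integer"),
                   rng_seed = rng_seed)
      })
      counts$drugs_scored <- sum(!is.na(drip$drip_mean))
      write.table(drip, file.path(out_dir, "drip.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }

    inputs <- c(embeddings = emb_path, terms = terms_path,
                ranking = ranking_path %||% NA, cases = cases_path %||% NA,
                frequencies = freq_path %||% NA)
    inputs <- inputs[!is.na(inputs)]
    manifest <- list(
      package_version = as.character(utils::packageVersion("saedr")),
      config = as.list(config),
      rng_seed = rng_seed,
      input_digests = as.list(tools::md5sum(inputs)),
      stage_timings_s = timings,
      counts = counts)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(severity = severity, drip = drip, manifest = manifest)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    saedr_stop("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
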