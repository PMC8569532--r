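# Shared fixture builders (all programmatic; nothing on disk).

# write a word2vec-style text file; vecs is a named list/matrix
write_embedding_fixture <- function(rows, header = NULL) {
  f <- tempfile(fileext = ".txt")
  writeLines(c(header, rows), f)
  f
}

# lexicon straight from a named vector matrix (one single-token term per row)
lexicon_from_matrix <- function(V, pt_id = NULL) {
  tt <- data.frame(term = rownames(V),
                   tokens = rownames(V),
                   pt_id = pt_id %||% paste0("PT_", rownames(V)),
                   stringsAsFactors = FALSE)
  rows <- paste(rownames(V), apply(V, 1, paste, collapse = " "))
  f <- write_embedding_fixture(rows)
  build_lexicon(tt, load_embeddings(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal seed_sets without the filtering pathway (tests of the walk engine)
raw_seed_sets <- function(severe, benign, source_id = "fixture") {
  structure(list(severe = severe, benign = benign,
                 source_id = source_id, pct = NA_real_),
            class = "seed_sets")
}

# walk_tally assembled by hand from dense per-walk visit matrices
tally_from_matrices <- function(terms, Vs, Vb, start_severe, start_benign) {
  Ms <- Matrix::Matrix(Vs, sparse = TRUE)
  Mb <- Matrix::Matrix(Vb, sparse = TRUE)
  structure(list(terms = terms,
                 s = as.numeric(Matrix::colSums(Ms)),
                 b = as.numeric(Matrix::colSums(Mb)),
                 visits_severe = Ms, visits_benign = Mb,
                 start_severe = start_severe, start_benign = start_benign,
                 seeds = raw_seed_sets(terms[unique(start_severe)],
                                       terms[unique(start_benign)]),
                 cfg = walk_config(1, 1, 1),
                 unreachable = rep(FALSE, length(terms)),
                 unvisited = rep(FALSE, length(terms))),
            class = "walk_tally")
}

# synthetic case_set built record by record
case_set_fixture <- function(...) {
  as_case_set(list(...))
}

# variant taking a ready-made list of records
case_set_fixture2 <- function(recs) {
  as_case_set(recs)
}
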