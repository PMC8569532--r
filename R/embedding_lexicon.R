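#' Load a word2vec-style text embedding model
#'
#' Reads a whitespace-separated text file with one token per row followed by
#' its vector components.  An optional first line holding just two integers
#' (`n_tokens dim`) is treated as a header and skipped.  Tokens are lowercased
#' at load; duplicate tokens keep their first vector (with a warning) and
#' all-zero vectors are rejected with a warning, since cosine similarity is
#' undefined for them.
#'
#' @param path path to the embedding file.
#' @param format_id format label; only `"word2vec_text"` is recognized.
#' @return An `embedding_space` object: list with `tokens` (character),
#'   `vectors` (numeric matrix, one row per token, rownames = tokens) and
#'   `dim` (integer).
#' @examples
#' f <- tempfile()
#' writeLines(c("2 3", "pain 0.1 0.2 0.3", "death 0.4 0.5 0.6"), f)
#' sp <- load_embeddings(f)
#' sp$dim
#' @export
load_embeddings <- function(path, format_id = "word2vec_text") {
  if (!identical(format_id, "word2vec_text")) {
    saedr_stop("unknown embedding format '%s'", format_id)
  }
  if (!file.exists(path)) saedr_stop("embedding file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) saedr_stop("embedding file is empty: %s", path)

  fields <- strsplit(trimws(lines), "[ \t]+")
  offset <- 0L
  # header line: exactly two fields, both integral
  if (length(fields[[1L]]) == 2L &&
      !anyNA(suppressWarnings(as.integer(fields[[1L]])))) {
    offset <- 1L
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) saedr_stop("embedding file has no vector rows: %s", path)

  nf <- lengths(fields)
  dim <- nf[1L] - 1L
  if (dim < 1L) saedr_stop("malformed embedding row at line %d: no vector components", offset + 1L)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    saedr_stop("malformed embedding row at line %d: expected %d fields, found %d",
               offset + bad[1L], nf[1L], nf[bad[1L]])
  }

  tokens <- tolower(vapply(fields, `[[`, "", 1L))
  vecs <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v
  }, numeric(dim))
  vecs <- t(vecs)
  nonnum <- which(apply(vecs, 1L, anyNA))
  if (length(nonnum) > 0L) {
    saedr_stop("malformed embedding row at line %d: non-numeric vector component",
               offset + nonnum[1L])
  }

  dup <- duplicated(tokens)
  if (any(dup)) {
    warning(sprintf("%d duplicate token(s) in embedding file; keeping first occurrence (e.g. '%s')",
                    sum(dup), tokens[dup][1L]), call. = FALSE)
    vecs <- vecs[!dup, , drop = FALSE]
    tokens <- tokens[!dup]
  }
  zero <- rowSums(vecs != 0) == 0L
  if (any(zero)) {
    warning(sprintf("%d all-zero vector(s) rejected at load (e.g. '%s')",
                    sum(zero), tokens[zero][1L]), call. = FALSE)
    vecs <- vecs[!zero, , drop = FALSE]
    tokens <- tokens[!zero]
  }
  rownames(vecs) <- tokens
  structure(list(tokens = tokens, vectors = vecs, dim = dim),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %d tokens, dim %d\n", length(x$tokens), x$dim))
  invisible(x)
}

#' Phrase vector as the mean of in-vocabulary token vectors
#'
#' Multi-word ADR terms are represented by the arithmetic mean of their token
#' embeddings (e.g. the vector for "abdominal pain" is
#' (v_abdominal + v_pain)/2).  Out-of-vocabulary tokens are skipped; if no
#' token is in vocabulary the phrase has no vector and `NULL` is returned.
#'
#' @param tokens character vector of tokens (order-irrelevant: a mean).
#' @param space an `embedding_space`.
#' @return numeric vector of length `space$dim`, or `NULL` if every token is
#'   out of vocabulary.
#' @export
phrase_vector <- function(tokens, space) {
  stopifnot(inherits(space, "embedding_space"))
  if (length(tokens) == 0L) saedr_stop("phrase_vector: empty token list")
  tokens <- tolower(tokens)
  hit <- tokens[tokens %in% rownames(space$vectors)]
  if (length(hit) == 0L) return(NULL)
  if (length(hit) == 1L) return(space$vectors[hit, ])
  colMeans(space$vectors[hit, , drop = FALSE])
}

#' Build the ADR lexicon: per-term vectors and preferred-term mapping
#'
#' Resolves each row of a term table (MedDRA-style lowest-level terms) against
#' an embedding space: terms whose tokens are at least partly in vocabulary
#' get a phrase vector, the rest are retained but flagged vector-less (they
#' are excluded from the lexical network downstream).  Coverage is the
#' fraction of input terms with a vector.
#'
#' @param term_table data.frame with columns `term`, `tokens` (pipe-separated
#'   token string) and `pt_id`, or a path to a TSV with those columns.
#' @param space an `embedding_space`.
#' @return A `lexicon` object: list with `records` (data.frame: term, pt_id,
#'   has_vector), `tokens` (list of token vectors per term), `vectors`
#'   (matrix over in-vocabulary terms, rownames = terms) and `coverage`.
#'   Coverage of an empty table is 0 by convention.
#' @export
build_lexicon <- function(term_table, space) {
  if (is.character(term_table) && length(term_table) == 1L) {
    term_table <- read.delim(term_table, sep = "\t", stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
  }
  need <- c("term", "tokens", "pt_id")
  miss <- setdiff(need, names(term_table))
  if (length(miss) > 0L) {
    saedr_stop("term table missing required column(s): %s", paste(miss, collapse = ", "))
  }
  stopifnot(inherits(space, "embedding_space"))

  n <- nrow(term_table)
  if (n == 0L) {
    return(structure(list(
      records = data.frame(term = character(), pt_id = character(),
                           has_vector = logical(), stringsAsFactors = FALSE),
      tokens = list(), vectors = matrix(numeric(), 0L, space$dim),
      coverage = 0), class = "lexicon"))
  }
  term <- tolower(as.character(term_table$term))
  pt_id <- as.character(term_table$pt_id)
  if (any(!nzchar(pt_id))) saedr_stop("empty pt_id in term table")
  toks <- strsplit(tolower(as.character(term_table$tokens)), "|", fixed = TRUE)

  vecs <- matrix(NA_real_, n, space$dim)
  has <- logical(n)
  for (i in seq_len(n)) {
    v <- phrase_vector(toks[[i]], space)
    if (!is.null(v)) {
      vecs[i, ] <- v
      has[i] <- TRUE
    }
  }
  dup <- duplicated(term)
  if (any(dup)) {
    warning(sprintf("%d duplicate term(s) in term table; keeping first", sum(dup)),
            call. = FALSE)
    term <- term[!dup]; pt_id <- pt_id[!dup]; toks <- toks[!dup]
    vecs <- vecs[!dup, , drop = FALSE]; has <- has[!dup]
    n <- length(term)
  }
  vm <- vecs[has, , drop = FALSE]
  rownames(vm) <- term[has]
  structure(list(
    records = data.frame(term = term, pt_id = pt_id, has_vector = has,
                         stringsAsFactors = FALSE),
    tokens = setNames(toks, term),
    vectors = vm,
    coverage = sum(has) / n), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d terms (%d with vectors, coverage %.1f%%), %d PTs\n",
              nrow(x$records), sum(x$records$has_vector), 100 * x$coverage,
              length(unique(x$records$pt_id))))
  invisible(x)
}

# internal: term -> pt_id lookup
lexicon_pt <- function(lexicon, terms) {
  m <- match(terms, lexicon$records$term)
  lexicon$records$pt_id[m]
}
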