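#' Build the weighted k-nearest-neighbor lexical network
#'
#' Connects every in-vocabulary term to its `k` nearest neighbors under
#' cosine distance; the edge weight is the cosine similarity of the two term
#' vectors, so weight increases with lexical-semantic closeness.  The k-NN
#' relation is symmetrized by union (an edge exists if either endpoint ranks
#' the other in its top k), which keeps the graph well connected for random
#' walks.  Non-positive cosine similarities are floored at `eps` so every
#' edge carries a usable positive transition weight.  Neighbor ties in
#' distance are broken by lexicographic term order for determinism.
#'
#' @param lexicon a `lexicon`; terms without vectors are excluded (logged).
#' @param k number of nearest neighbors per node; must be < number of nodes.
#' @param eps positive floor applied to edge weights (default 1e-8).
#' @return A `lexical_network` object: list with `nodes` (data.frame: term,
#'   pt_id), `edges` (data.frame: a, b, weight; a < b lexicographically,
#'   no self or parallel edges) and `k`.
#' @export
build_knn_network <- function(lexicon, k, eps = 1e-8) {
  stopifnot(inherits(lexicon, "lexicon"), k >= 1, eps > 0)
  k <- as.integer(k)
  excluded <- sum(!lexicon$records$has_vector)
  if (excluded > 0L) {
    saedr_log("excluding %d term(s) without vectors from the network", excluded)
  }
  V <- lexicon$vectors
  # deterministic node order regardless of input row order
  V <- V[order(rownames(V)), , drop = FALSE]
  n <- nrow(V)
  if (n < 2L) saedr_stop("need at least 2 terms with vectors, have %d", n)
  if (k >= n) saedr_stop("k (%d) must be smaller than the number of nodes (%d)", k, n)

  sims <- cosine_similarity_matrix(V)
  terms <- rownames(V)

  # per-node top-k by similarity; ties broken by lexicographic term order,
  # which is index order after the sort above
  ai <- integer(0); bi <- integer(0)
  for (i in seq_len(n)) {
    s <- sims[i, ]
    s[i] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    ai <- c(ai, rep.int(i, k)); bi <- c(bi, nb)
  }
  lo <- pmin(ai, bi); hi <- pmax(ai, bi)
  key <- paste0(lo, ":", hi)
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]
  w <- pmax(sims[cbind(lo, hi)], eps)
  o <- order(lo, hi)

  nodes <- data.frame(term = terms,
                      pt_id = lexicon_pt(lexicon, terms),
                      stringsAsFactors = FALSE)
  edges <- data.frame(a = terms[lo[o]], b = terms[hi[o]], weight = w[o],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, k = k), class = "lexical_network")
}

# internal: all-pairs cosine similarity of row vectors
cosine_similarity_matrix <- function(V) {
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) saedr_stop("zero-norm vector in lexicon; cannot compute cosine")
  U <- V / nrm
  S <- tcrossprod(U)
  # numerical guard: cosines live in [-1, 1]
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

#' @export
print.lexical_network <- function(x, ...) {
  cat(sprintf("<lexical_network> %d nodes, %d edges, k = %d\n",
              nrow(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

#' Write / read a lexical network as TSV edge + node lists
#'
#' The edge file has columns `node_a`, `node_b`, `weight`; the node file
#' `node_id`, `term`, `pt_id`.
#'
#' @param network a `lexical_network`.
#' @param edges_path,nodes_path output TSV paths (nodes file optional on read).
#' @return `write_network` returns the paths invisibly; `read_network`
#'   returns a `lexical_network` (with `k` recorded as `NA` if unknown).
#' @export
write_network <- function(network, edges_path, nodes_path) {
  stopifnot(inherits(network, "lexical_network"))
  ed <- network$edges
  names(ed) <- c("node_a", "node_b", "weight")
  write.table(ed, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- data.frame(node_id = seq_len(nrow(network$nodes)),
                   term = network$nodes$term, pt_id = network$nodes$pt_id,
                   stringsAsFactors = FALSE)
  write.table(nd, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges_path, nodes_path))
}

#' @rdname write_network
#' @param k neighbor parameter to record on read (metadata only).
#' @export
read_network <- function(edges_path, nodes_path = NULL, k = NA_integer_) {
  ed <- read.delim(edges_path, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(ed)))
  if (!is.null(nodes_path)) {
    nd <- read.delim(nodes_path, sep = "\t", stringsAsFactors = FALSE,
                     quote = "", comment.char = "")
    nodes <- data.frame(term = nd$term, pt_id = as.character(nd$pt_id),
                        stringsAsFactors = FALSE)
  } else {
    terms <- sort(unique(c(ed$node_a, ed$node_b)))
    nodes <- data.frame(term = terms, pt_id = NA_character_,
                        stringsAsFactors = FALSE)
  }
  edges <- data.frame(a = pmin(ed$node_a, ed$node_b),
                      b = pmax(ed$node_a, ed$node_b),
                      weight = ed$weight, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, k = as.integer(k)),
            class = "lexical_network")
}

# internal: adjacency list representation for the walk engine.
# Returns list(terms, nbr = list of integer neighbor vectors,
#              cw = list of cumulative weight vectors).
network_adjacency <- function(network) {
  terms <- network$nodes$term
  n <- length(terms)
  ia <- match(network$edges$a, terms)
  ib <- match(network$edges$b, terms)
  if (anyNA(ia) || anyNA(ib)) saedr_stop("edge endpoint missing from node table")
  w <- network$edges$weight
  if (any(w <= 0)) saedr_stop("non-positive edge weight in network")
  from <- c(ia, ib); to <- c(ib, ia); ww <- c(w, w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; ww <- ww[o]
  nbr <- split(to, factor(from, levels = seq_len(n)))
  wts <- split(ww, factor(from, levels = seq_len(n)))
  list(terms = terms, nbr = nbr,
       cw = lapply(wts, cumsum))
}

# internal: BFS over the adjacency from a set of start indices
reachable_from <- function(adj, starts) {
  n <- length(adj$terms)
  seen <- logical(n)
  queue <- unique(starts)
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    nxt <- unique(unlist(adj$nbr[queue], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  seen
}
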