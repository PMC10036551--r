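# Independent oracles and fixture builders shared across tests.

# Brute-force transitive-closure components: boolean reachability by
# repeated matrix squaring, independent of the igraph route used by the
# package.
oracle_families <- function(nodes, edges, threshold) {
  n <- length(nodes)
  M <- diag(TRUE, n)
  rownames(M) <- colnames(M) <- nodes
  if (nrow(edges)) {
    keep <- edges$weight >= threshold
    for (i in which(keep)) {
      M[edges$a[i], edges$b[i]] <- TRUE
      M[edges$b[i], edges$a[i]] <- TRUE
    }
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M > 0)) break
    M <- M2
  }
  groups <- apply(M, 1L, function(r) paste(nodes[r], collapse = "|"))
  fams <- lapply(unique(unname(groups)), function(g) sort(strsplit(g, "|", fixed = TRUE)[[1L]]))
  first <- vapply(fams, `[[`, "", 1L)
  fams[order(-lengths(fams), first)]
}

# similarity_graph built directly from an edge list (a, b, weight)
graph_from_edges <- function(edges, nodes = NULL) {
  hits <- data.frame(query_id = edges$a, subject_id = edges$b,
                     bitscore = edges$weight, stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    extra <- setdiff(nodes, c(edges$a, edges$b))
    if (length(extra))
      hits <- rbind(hits, data.frame(query_id = extra, subject_id = extra,
                                     bitscore = 0, stringsAsFactors = FALSE))
  }
  build_graph(hits, min_bitscore = 0, drop_self = TRUE)  # self rows only register nodes
}

# random weighted graph on `n` nodes; edge presence p, weights uniform
random_graph <- function(n, p = 0.3, wmin = 0, wmax = 100) {
  nodes <- sprintf("n%02d", seq_len(n))
  if (n < 2L) return(graph_from_edges(data.frame(a = character(), b = character(),
                                                 weight = numeric()), nodes))
  idx <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(idx)) < p
  edges <- data.frame(a = nodes[idx[1L, keep]], b = nodes[idx[2L, keep]],
                      weight = stats::runif(sum(keep), wmin, wmax),
                      stringsAsFactors = FALSE)
  graph_from_edges(edges, nodes)
}

# hits builder: mutual clique at a given bitscore
clique_hits <- function(ids, bits) {
  if (length(ids) < 2L) return(data.frame(query_id = ids, subject_id = ids,
                                          bitscore = bits))
  idx <- utils::combn(length(ids), 2L)
  data.frame(query_id = ids[idx[1L, ]], subject_id = ids[idx[2L, ]],
             bitscore = bits, stringsAsFactors = FALSE)
}

# a 12-column tabular line for parse_hits fixtures
hit_line <- function(q, s, bits) {
  paste(q, s, "95.0", "100", "0", "0", "1", "100", "1", "100", "1e-50",
        format(bits), sep = "\t")
}

# partition of emitted pairing members as a named label vector
pairing_labels <- function(res) {
  unlist(lapply(seq_along(res), function(i)
    stats::setNames(rep(i, length(res[[i]]$members)), res[[i]]$members)))
}
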