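#' Parse all-by-all pairwise similarity hits
#'
#' Reads BLAST/DIAMOND 12-column tabular output (outfmt 6 / m8): query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bitscore. Lines starting with
#' `#` and blank lines are skipped. Self-hits are retained at this stage;
#' [build_graph()] decides their fate.
#'
#' @param con A file path or text connection, or a character vector of lines.
#' @param min_columns Minimum number of tab-separated fields per line
#'   (default 12; the bitscore is always taken from column 12).
#' @return A data.frame with columns `query_id`, `subject_id`, `bitscore`,
#'   `identity_pct`, `evalue`, one row per hit in input order.
#' @examples
#' parse_hits("A\tB\t95.0\t100\t0\t0\t1\t100\t1\t100\t1e-50\t200.0")
#' @export
parse_hits <- function(con, min_columns = 12L) {
  lines <- if (is.character(con) &&
               (length(con) != 1L || (!file.exists(con) && grepl("\t", con)))) con
           else readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), identity_pct = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_columns)) {
    bad <- idx[which(nf < min_columns)[1L]]
    stop("parse error at line ", bad, ": expected >= ", min_columns,
         " tab-separated fields, found ", nf[which(nf < min_columns)[1L]])
  }
  qid <- vapply(fields, `[[`, "", 1L)
  sid <- vapply(fields, `[[`, "", 2L)
  bits <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  if (anyNA(bits)) {
    bad <- idx[which(is.na(bits))[1L]]
    stop("parse error at line ", bad, ": non-numeric bitscore")
  }
  if (any(bits < 0)) stop("negative bitscore encountered")
  if (any(!nzchar(qid)) || any(!nzchar(sid))) {
    bad <- idx[which(!nzchar(qid) | !nzchar(sid))[1L]]
    stop("parse error at line ", bad, ": empty identifier")
  }
  data.frame(query_id = qid, subject_id = sid, bitscore = bits,
             identity_pct = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
             evalue = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L))),
             stringsAsFactors = FALSE)
}

#' Build a symmetrized similarity graph from pairwise hits
#'
#' Nodes are all identifiers appearing as query or subject. Directional hits
#' for the same unordered pair are symmetrized by keeping the maximum
#' bitscore (multiple HSP rows likewise keep the max). Hits strictly below
#' `min_bitscore` are removed, matching the removal semantics of "bitscore
#' <50 were removed": a hit exactly at the threshold is kept.
#'
#' @param hits A data.frame as returned by [parse_hits()], or any data.frame
#'   with columns `query_id`, `subject_id`, `bitscore`.
#' @param min_bitscore Hits with symmetrized weight below this are dropped.
#' @param drop_self Remove self-hits (default TRUE).
#' @return An object of class `similarity_graph`: a list with `nodes`
#'   (character vector) and `edges` (data.frame `a`, `b`, `weight` with
#'   `a < b` lexicographically).
#' @export
build_graph <- function(hits, min_bitscore = 0, drop_self = TRUE) {
  stopifnot(min_bitscore >= 0)
  nodes <- sort(unique(c(hits$query_id, hits$subject_id)))
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  keep <- if (drop_self) a != b else rep(TRUE, length(a))
  a <- a[keep]; b <- b[keep]; w <- hits$bitscore[keep]
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    w <- tapply(w, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    w <- as.numeric(w)
    keep <- w >= min_bitscore
    a <- a[keep]; b <- b[keep]; w <- w[keep]
  } else w <- numeric()
  edges <- data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE,
                      row.names = NULL)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat("  bitscore range:", format(min(x$edges$weight)), "-",
        format(max(x$edges$weight)), "\n")
  invisible(x)
}

# igraph view of the qualifying subgraph at a bitscore threshold
.threshold_igraph <- function(graph, threshold) {
  e <- graph$edges[graph$edges$weight >= threshold, c("a", "b"), drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Single-linkage protein families at a bitscore threshold
#'
#' Families are the connected components of the subgraph keeping edges with
#' weight at or above `threshold`; isolated nodes form singleton families.
#' Families are ordered by descending size, ties broken by the
#' lexicographically smallest member id; members within a family are sorted.
#'
#' @param graph A `similarity_graph`.
#' @param threshold Bitscore threshold (>= 0).
#' @return An object of class `family_partition`: list with `families`
#'   (list of character vectors) and `threshold`.
#' @export
connected_families <- function(graph, threshold) {
  stopifnot(threshold >= 0)
  if (length(graph$nodes) == 0L)
    return(structure(list(families = list(), threshold = threshold),
                     class = "family_partition"))
  comp <- igraph::components(.threshold_igraph(graph, threshold))
  fams <- split(graph$nodes, comp$membership[graph$nodes])
  fams <- lapply(unname(fams), sort)
  first <- vapply(fams, `[[`, "", 1L)
  fams <- fams[order(-lengths(fams), first)]
  structure(list(families = fams, threshold = threshold),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  cat("family_partition at bitscore >=", x$threshold, ":",
      length(x$families), "families; sizes:",
      paste(utils::head(lengths(x$families), 10L), collapse = ", "),
      if (length(x$families) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.family_partition <- function(x, ...) {
  if (!length(x$families))
    return(data.frame(family_id = integer(), member_id = character(),
                      threshold = numeric()))
  data.frame(family_id = rep(seq_along(x$families), lengths(x$families)),
             member_id = unlist(x$families, use.names = FALSE),
             threshold = x$threshold, stringsAsFactors = FALSE)
}

#' Enzyme connectivity of a family
#'
#' The ratio of observed within-family edges with weight at or above the
#' threshold to the maximum possible number of pairs, n(n-1)/2. A singleton
#' family returns 1.0 by convention (singletons are filtered by size
#' elsewhere; this avoids 0/0).
#'
#' @param family Character vector of member ids (subset of `graph$nodes`).
#' @param graph A `similarity_graph`.
#' @param threshold Qualifying bitscore threshold.
#' @return A number in \[0, 1\].
#' @export
connectivity <- function(family, graph, threshold) {
  if (!all(family %in% graph$nodes))
    stop("family contains nodes absent from the graph: ",
         paste(setdiff(family, graph$nodes), collapse = ", "))
  n <- length(family)
  if (n <= 1L) return(1.0)
  e <- graph$edges
  within <- e$a %in% family & e$b %in% family & e$weight >= threshold
  sum(within) / (n * (n - 1) / 2)
}

#' Write a family partition as TSV
#'
#' Columns: family_id, member_id, threshold, connectivity (connectivity of
#' the member's family at the partition threshold).
#'
#' @param partition A `family_partition`.
#' @param graph The `similarity_graph` the partition came from.
#' @param path Output file path.
#' @export
write_families_tsv <- function(partition, graph, path) {
  df <- as.data.frame(partition)
  conn <- vapply(partition$families, connectivity, 0, graph = graph,
                 threshold = partition$threshold)
  df$connectivity <- if (nrow(df)) conn[df$family_id] else numeric()
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
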