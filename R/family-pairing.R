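#' Mining configuration
#'
#' Thresholds and floors for the recursive RRE-family / precursor-family
#' pairing algorithm. Defaults follow the published procedure: RRE hits
#' below 50 bits removed, ORF hits below 10 bits removed, families with
#' fewer than 30 members omitted, enzyme connectivity must exceed 0.2,
#' threshold escalation in steps of 10 bits, and a precursor family is
#' accepted when its size is within an order of magnitude of the enzyme
#' family's size.
#'
#' @param t0_rre Initial RRE bitscore threshold (bits).
#' @param t_orf ORF bitscore threshold (bits); never escalated.
#' @param min_family Minimum family size; applied at every recursion depth.
#' @param connectivity_min Families must have connectivity strictly above
#'   this to be evaluated for pairing.
#' @param t_step Threshold increment per recursion (bits).
#' @param size_ratio_bounds Acceptance bounds on precursor/enzyme size ratio.
#' @param max_iterations Maximum recursion depth per branch.
#' @param seed Seed recorded in the config (the algorithm is deterministic).
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(t0_rre = 50, t_orf = 10, min_family = 30L,
                          connectivity_min = 0.2, t_step = 10,
                          size_ratio_bounds = c(0.1, 10),
                          max_iterations = 50L, seed = 1L) {
  stopifnot(t0_rre >= 0, t_step > 0, min_family >= 1L,
            size_ratio_bounds[1] > 0, size_ratio_bounds[1] <= 1,
            size_ratio_bounds[2] >= 1)
  structure(list(t0_rre = t0_rre, t_orf = t_orf,
                 min_family = as.integer(min_family),
                 connectivity_min = connectivity_min, t_step = t_step,
                 size_ratio_bounds = size_ratio_bounds,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "mining_config")
}

#' @export
print.mining_config <- function(x, ...) {
  cat("mining_config: t0_rre =", x$t0_rre, "| t_orf =", x$t_orf,
      "| min_family =", x$min_family, "| connectivity_min =",
      x$connectivity_min, "| t_step =", x$t_step, "| ratio bounds [",
      x$size_ratio_bounds[1], ",", x$size_ratio_bounds[2], "]\n")
  invisible(x)
}

#' Initial RRE families
#'
#' Single-linkage families of the RRE similarity graph at the initial
#' threshold; families with fewer than `cfg$min_family` members are omitted.
#'
#' @param rre_graph A `similarity_graph` of RRE-containing proteins.
#' @param cfg A `mining_config`.
#' @return List of character vectors (member ids), descending size.
#' @export
initial_families <- function(rre_graph, cfg = mining_config()) {
  part <- connected_families(rre_graph, cfg$t0_rre)
  Filter(function(f) length(f) >= cfg$min_family, part$families)
}

#' Largest co-occurring precursor family of an RRE family
#'
#' Restricts the ORF similarity graph (edges at or above `cfg$t_orf`) to the
#' ORFs hosted in neighborhoods anchored by members of the family, and
#' returns the largest connected component (ties broken by smallest member
#' id). Family members without a neighborhood are skipped with a warning.
#'
#' @param family Character vector of RRE member ids.
#' @param orf_graph A `similarity_graph` over ORF ids.
#' @param neighborhoods Named list mapping anchor id to a character vector
#'   of hosted ORF ids (or to a `neighborhood` whose candidates carry ids).
#' @param cfg A `mining_config`.
#' @return Character vector of ORF ids (possibly length 1; length 0 only if
#'   no member hosts any ORF).
#' @export
largest_precursor_family <- function(family, orf_graph, neighborhoods,
                                     cfg = mining_config()) {
  covered <- family %in% names(neighborhoods)
  if (any(!covered))
    warning(sum(!covered), " family member(s) lack a neighborhood; skipped")
  hosted <- unlist(lapply(neighborhoods[family[covered]], function(nb) {
    if (inherits(nb, "neighborhood")) nb$candidates$orf_id else as.character(nb)
  }), use.names = FALSE)
  hosted <- unique(hosted)
  if (!length(hosted)) return(character())
  e <- orf_graph$edges
  e <- e[e$weight >= cfg$t_orf & e$a %in% hosted & e$b %in% hosted, ,
         drop = FALSE]
  g <- igraph::graph_from_data_frame(e[c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = hosted))
  comp <- igraph::components(g)
  fams <- split(hosted, comp$membership[hosted])
  fams <- lapply(unname(fams), sort)
  first <- vapply(fams, `[[`, "", 1L)
  fams[order(-lengths(fams), first)][[1L]]
}

#' Order-of-magnitude size test
#'
#' TRUE iff the precursor-to-enzyme family size ratio lies within the
#' configured bounds (default \[0.1, 10\]: "within an order of magnitude").
#'
#' @param precursor_size,rre_size Positive integers.
#' @param cfg A `mining_config`.
#' @export
size_ratio_ok <- function(precursor_size, rre_size, cfg = mining_config()) {
  if (precursor_size < 1L || rre_size < 1L) stop("sizes must be >= 1")
  r <- precursor_size / rre_size
  r >= cfg$size_ratio_bounds[1] && r <= cfg$size_ratio_bounds[2]
}

# maximum edge weight among edges internal to `members` (-Inf if none)
.max_internal_weight <- function(graph, members) {
  e <- graph$edges
  w <- e$weight[e$a %in% members & e$b %in% members]
  if (length(w)) max(w) else -Inf
}

# re-cluster `members` at threshold t: components of the induced subgraph
.recluster <- function(graph, members, t) {
  e <- graph$edges
  e <- e[e$weight >= t & e$a %in% members & e$b %in% members, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = members))
  comp <- igraph::components(g)
  fams <- split(members, comp$membership[members])
  fams <- lapply(unname(fams), sort)
  first <- vapply(fams, `[[`, "", 1L)
  fams[order(-lengths(fams), first)]
}

#' Recursive pairing of RRE families with precursor families
#'
#' The core mining algorithm. Each initial RRE family enters a depth-first
#' recursion at the starting threshold. At threshold t a family is:
#' dropped if smaller than `min_family`; split (re-clustered at t + t_step
#' and recursed) if its enzyme connectivity at t is at or below
#' `connectivity_min`; otherwise its largest co-occurring precursor family
#' is computed, and the pairing is emitted as accepted when the precursor
#' family's size is within the configured ratio bounds of the enzyme
#' family's size — failing that, the family is re-entered at t + t_step.
#' A branch terminates, emitting nothing, when the escalated threshold
#' exceeds the family's maximum internal edge weight or the recursion depth
#' exceeds `max_iterations`.
#'
#' @param rre_graph `similarity_graph` over RRE protein ids (built with
#'   hits below `cfg$t0_rre` removed).
#' @param orf_graph `similarity_graph` over ORF ids (hits below `cfg$t_orf`
#'   removed).
#' @param neighborhoods Named list: anchor id -> hosted ORF ids (or
#'   `neighborhood` objects).
#' @param cfg A `mining_config`.
#' @return An object of class `paired_families`: a list of results, each
#'   with `members`, `threshold`, `connectivity`, `precursor_members`,
#'   `threshold_history`, `accepted`; plus the config as an attribute.
#' @export
pair_families <- function(rre_graph, orf_graph, neighborhoods,
                          cfg = mining_config()) {
  results <- list()
  emit <- function(res) results[[length(results) + 1L]] <<- res

  recurse <- function(members, t, history, root_id, depth) {
    history <- c(history, t)
    if (length(members) < cfg$min_family) return(invisible())
    if (depth > cfg$max_iterations) return(invisible())
    conn <- connectivity(members, rre_graph, t)
    descend <- function() {
      t2 <- t + cfg$t_step
      if (t2 > .max_internal_weight(rre_graph, members)) return(invisible())
      for (sub in .recluster(rre_graph, members, t2))
        recurse(sub, t2, history, root_id, depth + 1L)
    }
    if (conn <= cfg$connectivity_min) {
      descend()
    } else {
      prec <- largest_precursor_family(members, orf_graph, neighborhoods, cfg)
      if (length(prec) >= 1L &&
          size_ratio_ok(length(prec), length(members), cfg)) {
        emit(list(members = sort(members), threshold = t, connectivity = conn,
                  precursor_members = prec, threshold_history = history,
                  accepted = TRUE, root_family = root_id))
      } else {
        descend()
      }
    }
    invisible()
  }

  fams <- initial_families(rre_graph, cfg)
  for (i in seq_along(fams))
    recurse(fams[[i]], cfg$t0_rre, numeric(), i, 1L)
  structure(results, class = "paired_families", config = cfg)
}

#' @export
print.paired_families <- function(x, ...) {
  cat("paired_families:", length(x), "accepted pairing(s)\n")
  for (i in seq_along(x)) {
    r <- x[[i]]
    cat(sprintf("  [%d] %d enzymes (t=%g, connectivity %.2f) <-> %d precursor ORFs; history: %s\n",
                i, length(r$members), r$threshold, r$connectivity,
                length(r$precursor_members),
                paste(r$threshold_history, collapse = " -> ")))
  }
  invisible(x)
}

#' @export
summary.paired_families <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Recursive RRE/precursor family pairing\n")
  print(attr(object, "config"))
  if (nrow(df)) print(df) else cat("no accepted pairings\n")
  invisible(df)
}

#' @export
as.data.frame.paired_families <- function(x, ...) {
  if (!length(x))
    return(data.frame(pairing = integer(), n_enzymes = integer(),
                      n_precursors = integer(), threshold = numeric(),
                      connectivity = numeric(), ratio = numeric(),
                      history = character()))
  data.frame(
    pairing = seq_along(x),
    n_enzymes = vapply(x, function(r) length(r$members), 0L),
    n_precursors = vapply(x, function(r) length(r$precursor_members), 0L),
    threshold = vapply(x, `[[`, 0, "threshold"),
    connectivity = vapply(x, `[[`, 0, "connectivity"),
    ratio = vapply(x, function(r)
      length(r$precursor_members) / length(r$members), 0),
    history = vapply(x, function(r)
      paste(r$threshold_history, collapse = ","), ""),
    stringsAsFactors = FALSE)
}
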