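# End-to-end orchestration: harvest -> graphs -> pairing -> profile -> report.

.log_msg <- function(level, ..., verbose = TRUE) {
  if (!verbose && level == "info") return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

#' Run the end-to-end mining pipeline
#'
#' Loads input paths from a flat YAML config (or an equivalent named list),
#' harvests short-ORF candidates from the gene neighborhoods around each
#' anchor, builds the RRE and ORF similarity graphs from the 12-column hit
#' tables, runs the recursive family-pairing algorithm, and profiles the
#' precursor candidates of every accepted pairing. Zero accepted families
#' is a successful (empty) outcome.
#'
#' Recognized config keys: `rre_hits`, `orf_hits` (hit table paths,
#' required), `genomes` (nucleotide FASTA), `annotations` (GFF3),
#' `anchor_ids` (one id per line), `k` (gene window half-width, default 8),
#' `min_aa`/`max_aa` (ORF length bounds, defaults 5/119), `cterm_residue`
#' (default "T"), plus any [mining_config()] field.
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Optional directory to write the JSON + TSV report into.
#' @param verbose Log progress to stderr.
#' @return An object of class `mining_report`.
#' @export
run_mine <- function(config, out_dir = NULL, verbose = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  req <- c("rre_hits", "orf_hits")
  for (key in req) if (is.null(cfg[[key]]))
    stop("config is missing required key '", key, "'")
  for (key in intersect(c("rre_hits", "orf_hits", "genomes", "annotations",
                          "anchor_ids"), names(cfg)))
    if (is.character(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("input path for '", key, "' does not exist: ", cfg[[key]])

  mcfg_keys <- intersect(names(cfg), names(formals(mining_config)))
  mcfg <- do.call(mining_config, cfg[mcfg_keys])
  k <- if (is.null(cfg$k)) 8L else as.integer(cfg$k)
  min_aa <- if (is.null(cfg$min_aa)) 5L else as.integer(cfg$min_aa)
  max_aa <- if (is.null(cfg$max_aa)) 119L else as.integer(cfg$max_aa)
  cterm <- if (is.null(cfg$cterm_residue)) "T" else cfg$cterm_residue

  .log_msg("info", "building similarity graphs", verbose = verbose)
  rre_graph <- build_graph(parse_hits(cfg$rre_hits), mcfg$t0_rre)
  orf_graph <- build_graph(parse_hits(cfg$orf_hits), mcfg$t_orf)

  anchor_ids <- if (!is.null(cfg$anchor_ids)) readLines(cfg$anchor_ids)
                else rre_graph$nodes
  neighborhoods <- list()
  orf_seqs <- character()
  if (!is.null(cfg$genomes) && !is.null(cfg$annotations)) {
    .log_msg("info", "harvesting neighborhoods for ", length(anchor_ids),
             " anchors", verbose = verbose)
    genomes <- load_genome(cfg$annotations, cfg$genomes)
    for (ct in names(genomes)) {
      genes <- genomes[[ct]]$genes
      for (a in intersect(anchor_ids, genes$gene_id)) {
        nb <- extract_window(genes, a, k)
        nb <- harvest_neighborhood(nb, genomes[[ct]]$sequence,
                                   min_aa = min_aa, max_aa = max_aa,
                                   exclusion_ids = anchor_ids)
        neighborhoods[[a]] <- nb
        orf_seqs[nb$candidates$orf_id] <- nb$candidates$aa_sequence
      }
    }
  } else if (!is.null(cfg$neighborhoods)) {
    neighborhoods <- cfg$neighborhoods
    orf_seqs <- if (!is.null(cfg$orf_seqs)) cfg$orf_seqs else character()
  } else stop("config must supply genomes+annotations or precomputed neighborhoods")

  .log_msg("info", "pairing families", verbose = verbose)
  pairings <- pair_families(rre_graph, orf_graph, neighborhoods, mcfg)

  profiles <- lapply(seq_along(pairings), function(i) {
    r <- pairings[[i]]
    seqs <- orf_seqs[intersect(r$precursor_members, names(orf_seqs))]
    kept <- filter_cterm(unname(seqs), cterm)
    host <- vapply(names(seqs), function(id) {
      hit <- vapply(neighborhoods[r$members], function(nb) {
        ids <- if (inherits(nb, "neighborhood")) nb$candidates$orf_id else nb
        id %in% ids
      }, NA)
      names(which(hit))[1]
    }, "")
    list(pairing = i,
         n_candidates = length(seqs),
         n_cterm = length(kept),
         pfm = if (length(kept)) build_pfm(kept, min(nchar(kept))) else NULL,
         bgc_stats = per_bgc_stats(host))
  })

  report <- structure(list(
    pairings = pairings,
    profiles = profiles,
    diagnostics = as.data.frame(pairings),
    config = c(cfg[setdiff(names(cfg), "neighborhoods")],
               list(mining = unclass(mcfg))),
    n_anchors = length(anchor_ids),
    n_neighborhoods = length(neighborhoods)),
    class = "mining_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mining_report <- function(x, ...) {
  cat("mining_report:", length(x$pairings), "accepted pairing(s) from",
      x$n_neighborhoods, "neighborhoods /", x$n_anchors, "anchors\n")
  if (length(x$pairings)) print(x$diagnostics)
  invisible(x)
}

#' Write a mining report as JSON and TSV
#'
#' @param report A `mining_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- lapply(seq_along(report$pairings), function(i) {
    r <- report$pairings[[i]]
    list(pairing = i, members = r$members, threshold = r$threshold,
         connectivity = r$connectivity,
         precursor_members = r$precursor_members,
         threshold_history = r$threshold_history, accepted = r$accepted)
  })
  jsonlite::write_json(
    list(results = res,
         config = report$config[vapply(report$config, is.atomic, NA)]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$diagnostics, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Pair families directly from an in-memory synthetic bundle
#'
#' Convenience route for recovery testing: builds both similarity graphs
#' from the bundle's hit tables, maps each anchor to its planted ORF ids,
#' and runs [pair_families()]. (The full pipeline route instead harvests
#' ORFs from the generated genomes; see [run_mine()].)
#'
#' @param bundle A `sim_bundle` from [simulate_daptides()].
#' @param mcfg A [mining_config()].
#' @return A `paired_families` object.
#' @export
mine_bundle <- function(bundle, mcfg = mining_config()) {
  rre_graph <- build_graph(bundle$rre_hits, mcfg$t0_rre)
  orf_graph <- build_graph(bundle$orf_hits, mcfg$t_orf)
  nbs <- split(bundle$truth$planted_orfs$orf_id,
               bundle$truth$planted_orfs$anchor_id)
  pair_families(rre_graph, orf_graph, nbs, mcfg)
}

#' Percent hemolysis from absorbance readings
#'
#' Normalizes the A410 absorbance of a test sample between the DMSO
#' (vehicle, 0%) and Triton X-100 (full lysis, 100%) controls:
#' 100 * (abs_test - abs_dmso) / (abs_triton - abs_dmso).
#'
#' @param abs_test Absorbance of the test sample (vectorized).
#' @param abs_dmso Absorbance of the DMSO control.
#' @param abs_triton Absorbance of the Triton X-100 control.
#' @return Percent hemolysis.
#' @export
hemolysis_percent <- function(abs_test, abs_dmso, abs_triton) {
  if (abs_triton == abs_dmso)
    stop("Triton and DMSO absorbances are equal; normalization undefined")
  100 * (abs_test - abs_dmso) / (abs_triton - abs_dmso)
}
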