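# Deterministic generator of synthetic genomes, neighborhoods and pairwise
# bitscore tables with planted family structure, for recovery testing of the
# mining pipeline without any external data.

.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W")

# alphabetically first codon per amino acid under genetic code 11
.codon_table <- function() {
  gc11 <- Biostrings::getGeneticCode("11")
  gc11 <- gc11[gc11 != "*"]
  codons <- sort(names(gc11))
  tab <- tapply(codons, gc11[codons], `[[`, 1L)
  as.list(tab)
}

.reverse_translate <- function(pep, codons = .codon_table()) {
  aas <- strsplit(pep, "")[[1L]]
  paste0(paste(unlist(codons[aas]), collapse = ""), "TAA")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.sample1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length-1 x

.random_peptide <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                               collapse = "")

#' Simulation configuration for the synthetic dataset generator
#'
#' Defines the planted ground truth: number and sizes of RRE families,
#' precursor ORFs per cluster, the leader motif and C-terminal residue, and
#' the two-component bitscore distribution (high within planted families,
#' low and sparse between them). Defaults describe clean separation: three
#' families of sizes 40/35/30, within-family bitscores N(120, 20) and
#' between-family bitscores N(20, 10) present for 0.5% of pairs.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param family_sizes Integer vector, one RRE family per entry.
#' @param precursors_per_bgc Integer range (min, max) of precursor ORFs per
#'   cluster; default 1-4.
#' @param leader_motif Conserved leader motif (default "ELEAMEAP"); every
#'   precursor is M + motif + hydrophobic core + `cterm_residue`.
#' @param core_length Integer range of core lengths.
#' @param cterm_residue Invariant C-terminal residue (default "T").
#' @param mu_in,sigma_in Within-family bitscore Normal parameters.
#' @param mu_out,sigma_out Between-family bitscore Normal parameters.
#' @param p_between Probability that an unrelated pair has any hit at all.
#' @param n_decoy_orfs_per_bgc Planted decoy short ORFs per cluster.
#' @param bridges Optional data.frame (`family_a`, `family_b`, `bitscore`)
#'   of planted inter-family bridge edges (stress testing).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, family_sizes = c(40L, 35L, 30L),
                       precursors_per_bgc = c(1L, 4L),
                       leader_motif = "ELEAMEAP",
                       core_length = c(6L, 15L),
                       cterm_residue = "T",
                       mu_in = 120, sigma_in = 20,
                       mu_out = 20, sigma_out = 10,
                       p_between = 0.005,
                       n_decoy_orfs_per_bgc = 2L,
                       bridges = NULL) {
  stopifnot(mu_in > mu_out, all(family_sizes >= 1L),
            precursors_per_bgc[1] >= 1L,
            precursors_per_bgc[2] >= precursors_per_bgc[1],
            p_between >= 0, p_between <= 1)
  structure(list(seed = as.integer(seed),
                 n_families = length(family_sizes),
                 family_sizes = as.integer(family_sizes),
                 precursors_per_bgc = as.integer(precursors_per_bgc),
                 leader_motif = leader_motif,
                 core_length = as.integer(core_length),
                 cterm_residue = cterm_residue,
                 mu_in = mu_in, sigma_in = sigma_in,
                 mu_out = mu_out, sigma_out = sigma_out,
                 p_between = p_between,
                 n_decoy_orfs_per_bgc = as.integer(n_decoy_orfs_per_bgc),
                 bridges = bridges),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_families, "families (",
      paste(x$family_sizes, collapse = "/"), ") | bitscores in N(",
      x$mu_in, ",", x$sigma_in, ") out N(", x$mu_out, ",", x$sigma_out,
      ") p_between", x$p_between, "\n")
  invisible(x)
}

# 12-column tabular rows for a set of symmetric base scores, both directions
# with +/-5% multiplicative jitter; optional self-hits
.hit_rows <- function(a, b, base, self_ids = character(), self_score = 300) {
  jit1 <- stats::runif(length(base), 0.95, 1.05)
  jit2 <- stats::runif(length(base), 0.95, 1.05)
  row <- function(q, s, bits) data.frame(
    query_id = q, subject_id = s, identity_pct = 90, length = 100,
    mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 1e-30, bitscore = round(bits, 1), stringsAsFactors = FALSE)
  out <- rbind(row(a, b, pmax(0, base * jit1)),
               row(b, a, pmax(0, base * jit2)))
  if (length(self_ids))
    out <- rbind(out, row(self_ids, self_ids, self_score))
  out
}

# symmetric scores for all unordered pairs of `ids`, split by same-group:
# within pairs always present ~ N(mu_in, sd_in); between pairs present with
# prob p ~ N(mu_out, sd_out); returns data.frame a, b, base
.pair_scores <- function(ids, group, mu_in, sd_in, mu_out, sd_out, p) {
  n <- length(ids)
  if (n < 2L) return(data.frame(a = character(), b = character(), base = numeric()))
  idx <- utils::combn(n, 2L)
  a <- ids[idx[1L, ]]; b <- ids[idx[2L, ]]
  same <- group[idx[1L, ]] == group[idx[2L, ]]
  keep <- same | (stats::runif(length(a)) < p)
  base <- ifelse(same, stats::rnorm(length(a), mu_in, sd_in),
                 stats::rnorm(length(a), mu_out, sd_out))
  data.frame(a = a[keep], b = b[keep], base = pmax(0, base[keep]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dataset bundle with planted family structure
#'
#' Produces, per anchor, one biosynthetic gene cluster on its own contig:
#' seven annotated genes (the RRE anchor in the middle) with the planted
#' precursor ORFs — M + leader motif + hydrophobic-biased core + invariant
#' C-terminal residue — and decoy short ORFs encoded as real reading frames
#' (reverse-translated with genetic code 11, stop TAA, forward strand, an
#' in-frame TAATAA guard immediately upstream of each planted start) in the
#' intergenic space downstream of the anchor. Pairwise bitscore tables for
#' the RRE proteins and for the ORFs are drawn from the configured
#' two-component distribution and written in 12-column tabular form in both
#' directions with small asymmetric jitter, self-hits included.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_bundle`: `config`, `genomes` (contig ->
#'   list(sequence, genes)), `anchors` (data.frame), `anchor_proteins`
#'   (named character), `rre_hits` / `orf_hits` (12-column data.frames),
#'   and `truth` (`protein_family`, `orf_family` — planted label or
#'   "decoy" —, `planted_orfs` data.frame).
#' @export
simulate_daptides <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  codons <- .codon_table()
  fam_label <- paste0("F", seq_len(cfg$n_families))
  genomes <- list()
  anchors <- list()
  planted <- list()
  orf_ids <- character(); orf_group <- character()

  for (i in seq_len(cfg$n_families)) {
    for (j in seq_len(cfg$family_sizes[i])) {
      anchor_id <- sprintf("F%d_A%03d", i, j)
      contig <- sprintf("ctg_F%d_%03d", i, j)
      n_prec <- .sample1(seq(cfg$precursors_per_bgc[1],
                             cfg$precursors_per_bgc[2]))
      peps <- c(
        vapply(seq_len(n_prec), function(p) paste0(
          "M", cfg$leader_motif,
          .random_peptide(.sample1(seq(cfg$core_length[1], cfg$core_length[2])),
                          .HYDROPHOBIC),
          cfg$cterm_residue), ""),
        vapply(seq_len(cfg$n_decoy_orfs_per_bgc), function(d) paste0(
          "M", .random_peptide(.sample1(10:25),
                               setdiff(LETTERS[LETTERS %in% names(.RESIDUE_FORMULA)],
                                       cfg$cterm_residue))), ""))
      is_prec <- c(rep(TRUE, n_prec), rep(FALSE, cfg$n_decoy_orfs_per_bgc))

      segs <- character(); cur <- 0L
      genes <- list()
      push <- function(s) { segs[[length(segs) + 1L]] <<- s; cur <<- cur + nchar(s) }
      add_gene <- function(id, product) {
        push(.random_dna(40L))
        st <- cur + 1L
        push(.random_dna(300L))
        genes[[length(genes) + 1L]] <<- data.frame(
          gene_id = id, contig_id = contig, start = st, end = cur,
          strand = "+", product = product, stringsAsFactors = FALSE)
      }
      for (g in 1:3) add_gene(paste0(contig, "_g", g), "hypothetical protein")
      add_gene(anchor_id, "RRE-peptidase fusion")
      orf_rec <- list()
      for (p in seq_along(peps)) {
        push(.random_dna(20L))
        push("TAATAA")
        st <- cur + 1L
        push(.reverse_translate(peps[p], codons))
        orf_rec[[p]] <- data.frame(
          orf_id = sprintf("%s_%d_%d_+", contig, st, cur),
          anchor_id = anchor_id, contig_id = contig,
          start = st, end = cur, strand = "+",
          aa_sequence = peps[p],
          family = if (is_prec[p]) fam_label[i] else "decoy",
          stringsAsFactors = FALSE)
      }
      push(.random_dna(20L))
      for (g in 5:7) add_gene(paste0(contig, "_g", g), "hypothetical protein")
      push(.random_dna(40L))

      genomes[[contig]] <- list(sequence = paste(segs, collapse = ""),
                                genes = do.call(rbind, genes))
      anchors[[anchor_id]] <- data.frame(
        anchor_id = anchor_id, contig_id = contig, family = fam_label[i],
        stringsAsFactors = FALSE)
      rec <- do.call(rbind, orf_rec)
      planted[[anchor_id]] <- rec
      orf_ids <- c(orf_ids, rec$orf_id)
      orf_group <- c(orf_group, rec$family)
    }
  }
  anchors <- do.call(rbind, anchors); rownames(anchors) <- NULL
  planted <- do.call(rbind, planted); rownames(planted) <- NULL

  anchor_proteins <- vapply(anchors$anchor_id, function(a)
    .random_peptide(120L, names(.RESIDUE_FORMULA)), "")

  rre_pairs <- .pair_scores(anchors$anchor_id, anchors$family,
                            cfg$mu_in, cfg$sigma_in, cfg$mu_out, cfg$sigma_out,
                            cfg$p_between)
  if (!is.null(cfg$bridges)) {
    for (r in seq_len(nrow(cfg$bridges))) {
      fa <- anchors$anchor_id[anchors$family == cfg$bridges$family_a[r]][1L]
      fb <- anchors$anchor_id[anchors$family == cfg$bridges$family_b[r]][1L]
      rre_pairs <- rbind(rre_pairs, data.frame(
        a = fa, b = fb, base = cfg$bridges$bitscore[r] / 1.05,
        stringsAsFactors = FALSE))
    }
  }
  rre_hits <- .hit_rows(rre_pairs$a, rre_pairs$b, rre_pairs$base,
                        self_ids = anchors$anchor_id,
                        self_score = 2 * cfg$mu_in)

  # decoys form no coherent group: give each decoy its own label
  orf_group[orf_group == "decoy"] <- paste0("decoy_", seq_len(sum(orf_group == "decoy")))
  orf_pairs <- .pair_scores(orf_ids, orf_group,
                            cfg$mu_in, cfg$sigma_in, cfg$mu_out, cfg$sigma_out,
                            cfg$p_between)
  orf_hits <- .hit_rows(orf_pairs$a, orf_pairs$b, orf_pairs$base,
                        self_ids = orf_ids, self_score = 2 * cfg$mu_in)

  structure(list(
    config = cfg,
    genomes = genomes,
    anchors = anchors,
    anchor_proteins = anchor_proteins,
    rre_hits = rre_hits,
    orf_hits = orf_hits,
    truth = list(
      protein_family = stats::setNames(anchors$family, anchors$anchor_id),
      orf_family = stats::setNames(planted$family, planted$orf_id),
      planted_orfs = planted)),
    class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", nrow(x$anchors), "anchors in", x$config$n_families,
      "families;", nrow(x$truth$planted_orfs), "planted ORFs (",
      sum(x$truth$orf_family != "decoy"), "precursors );",
      nrow(x$rre_hits), "RRE hit rows,", nrow(x$orf_hits), "ORF hit rows\n")
  invisible(x)
}

#' Write a synthetic bundle to disk in standard formats
#'
#' Emits `genomes.fna` (multi-contig nucleotide FASTA), `annotations.gff3`,
#' `anchors.faa` (anchor protein FASTA), `anchor_ids.txt`, `rre_hits.tsv`
#' and `orf_hits.tsv` (12-column tabular), and `truth.json` — all consumed
#' unchanged by the mining pipeline. Byte-identical for identical configs.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(vapply(bundle$genomes, `[[`, "", "sequence"))
  Biostrings::writeXStringSet(seqs, file.path(dir, "genomes.fna"))
  genes <- do.call(rbind, lapply(bundle$genomes, `[[`, "genes"))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "CDS"; gr$ID <- genes$gene_id; gr$product <- genes$product
  gr$phase <- 0L
  rtracklayer::export(gr, file.path(dir, "annotations.gff3"), format = "gff3")
  aa <- Biostrings::AAStringSet(bundle$anchor_proteins)
  Biostrings::writeXStringSet(aa, file.path(dir, "anchors.faa"))
  writeLines(bundle$anchors$anchor_id, file.path(dir, "anchor_ids.txt"))
  wtab <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  wtab(bundle$rre_hits, file.path(dir, "rre_hits.tsv"))
  wtab(bundle$orf_hits, file.path(dir, "orf_hits.tsv"))
  jsonlite::write_json(list(
    protein_family = as.list(bundle$truth$protein_family),
    orf_family = as.list(bundle$truth$orf_family),
    planted_orfs = bundle$truth$planted_orfs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Derived stress configurations for recovery testing
#'
#' Three documented stress levels applied to a base configuration:
#' `high_noise` — ten-fold denser between-family hits (p_between 0.05,
#' between scores N(15, 8)); `low_separation` — within-family scores
#' lowered to N(60, 20) so a third of within edges fall below the initial
#' threshold; `bridged` — families 60/50/40/15/15 with one planted 55-bit
#' bridge between the two smallest families (a single spurious bridge
#' merges two small families; global recovery must stay high).
#'
#' @param cfg Base [sim_config()].
#' @return Named list of `sim_config` objects.
#' @export
stress_variants <- function(cfg = sim_config()) {
  high_noise <- cfg; high_noise$p_between <- 0.05
  high_noise$mu_out <- 15; high_noise$sigma_out <- 8
  low_sep <- cfg; low_sep$mu_in <- 60; low_sep$sigma_in <- 20
  stopifnot(low_sep$mu_in > low_sep$mu_out)
  bridged <- cfg
  bridged$family_sizes <- c(60L, 50L, 40L, 15L, 15L)
  bridged$n_families <- 5L
  bridged$bridges <- data.frame(family_a = "F4", family_b = "F5",
                                bitscore = 55)
  list(high_noise = high_noise, low_separation = low_sep, bridged = bridged)
}
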