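#' Load a genome: annotations plus nucleotide sequence
#'
#' Reads a GFF3 annotation file and a nucleotide FASTA and returns, per
#' contig, the sequence and the gene records sorted by start coordinate.
#' Features of type `gene` or `CDS` are used; where a gene and its CDS share
#' an ID, one record is kept. Coordinates are 1-based inclusive throughout
#' (GFF3 convention).
#'
#' @param gff Path to a GFF3 file.
#' @param fasta Path to a nucleotide FASTA file.
#' @return A named list (by contig id); each element is a list with
#'   `sequence` (character) and `genes` (data.frame with `gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `product`).
#' @export
load_genome <- function(gff, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "CDS")]
  contig <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(contig), names(seqs))
  if (length(missing))
    stop("GFF references contigs absent from FASTA: ",
         paste(missing, collapse = ", "))
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids <- ifelse(is.na(ids) | !nzchar(ids),
                paste0(contig, "_", GenomicRanges::start(gr)), ids)
  genes <- data.frame(
    gene_id = ids,
    contig_id = contig,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if (!is.null(gr$product)) as.character(gr$product)
              else rep(NA_character_, length(gr)),
    stringsAsFactors = FALSE)
  genes <- genes[!duplicated(genes[c("gene_id", "contig_id", "start", "end")]), ]
  if (anyDuplicated(paste(genes$contig_id, genes$gene_id)))
    stop("duplicate gene ids within a contig")
  out <- lapply(names(seqs), function(ct) {
    g <- genes[genes$contig_id == ct, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    rownames(g) <- NULL
    list(sequence = as.character(seqs[[ct]]), genes = g)
  })
  names(out) <- names(seqs)
  out
}

#' Extract the gene window around an anchor
#'
#' Returns the neighborhood of genes within `k` gene indices of the anchor
#' on its contig, truncated at contig ends, plus the nucleotide span covered.
#'
#' @param genes A gene data.frame (one contig, sorted by start) as produced
#'   by [load_genome()].
#' @param anchor_id Gene id of the RRE-containing anchor.
#' @param k Window half-width in genes (default 8, "within 8 genes").
#' @return An object of class `neighborhood`: list with `anchor_id`,
#'   `contig_id`, `genes` (the windowed data.frame), `span` (c(start, end)).
#' @export
extract_window <- function(genes, anchor_id, k = 8L) {
  i <- which(genes$gene_id == anchor_id)
  if (length(i) != 1L) stop("anchor '", anchor_id, "' not found (or ambiguous)")
  lo <- max(1L, i - k)
  hi <- min(nrow(genes), i + k)
  g <- genes[lo:hi, , drop = FALSE]
  rownames(g) <- NULL
  structure(list(anchor_id = anchor_id,
                 contig_id = genes$contig_id[i],
                 genes = g,
                 span = c(min(g$start), max(g$end)),
                 candidates = NULL),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat("neighborhood of", x$anchor_id, "on", x$contig_id, ":",
      nrow(x$genes), "genes, span", x$span[1], "-", x$span[2])
  if (!is.null(x$candidates)) cat(",", nrow(x$candidates), "ORF candidates")
  cat("\n")
  invisible(x)
}

.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.START_BONUS <- c(ATG = 0.5, GTG = 0.25, TTG = 0.0)

.gc11_env <- new.env(parent = emptyenv())
.gc11 <- function() {
  if (is.null(.gc11_env$code)) .gc11_env$code <- Biostrings::getGeneticCode("11")
  .gc11_env$code
}

# translate a vector of codons with genetic code 11; first codon forced to M
.translate_orf <- function(codons) {
  aa <- .gc11()[codons]
  aa[1L] <- "M"
  paste(aa, collapse = "")
}

# scan one oriented sequence (character), all 3 frames; returns data.frame of
# ORFs in scan coordinates (1-based, start codon .. stop codon inclusive)
.scan_frames <- function(seq, min_aa, max_aa) {
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < min_aa + 1L) next
    pos <- f + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, pos, pos + 2L)
    starts <- which(codons %in% .START_CODONS)
    stops <- which(codons %in% .STOP_CODONS)
    if (!length(starts) || !length(stops)) next
    # for each start, the next in-frame stop strictly after it
    nxt <- stops[findInterval(starts, stops) + 1L]
    ok <- !is.na(nxt)
    starts <- starts[ok]; nxt <- nxt[ok]
    len_aa <- nxt - starts            # residues, stop excluded
    keep <- len_aa >= min_aa & len_aa <= max_aa
    starts <- starts[keep]; nxt <- nxt[keep]; len_aa <- len_aa[keep]
    if (!length(starts)) next
    pep <- mapply(function(s, e) .translate_orf(codons[s:(e - 1L)]),
                  starts, nxt)
    has_n <- grepl("N", substring(seq, pos[starts], pos[nxt] + 2L), fixed = TRUE)
    if (any(has_n)) {
      warning(sum(has_n), " ORF(s) containing N skipped")
      starts <- starts[!has_n]; nxt <- nxt[!has_n]
      len_aa <- len_aa[!has_n]; pep <- pep[!has_n]
    }
    if (!length(starts)) next
    out[[length(out) + 1L]] <- data.frame(
      frame0 = f,
      scan_start = pos[starts],
      scan_end = pos[nxt] + 2L,
      aa_sequence = unname(pep),
      length_aa = len_aa,
      start_codon = codons[starts],
      stop_scan = pos[nxt],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Find short open reading frames in a nucleotide span
#'
#' Scans both strands in all three frames for start-codon-to-stop-codon ORFs
#' (starts ATG/GTG/TTG, translated with the bacterial genetic code, table 11,
#' initiator rendered as M; the stop codon is excluded from the peptide).
#' Coordinates are reported on the forward strand, 1-based inclusive, and
#' include the stop codon, so `end - start + 1 == 3 * (length_aa + 1)`.
#' ORFs containing N are skipped with a warning.
#'
#' @param dna Nucleotide sequence (character, A/C/G/T/N).
#' @param span Integer pair `c(start, end)` restricting the scan
#'   (default: the whole sequence).
#' @param min_aa,max_aa Peptide length bounds, inclusive (defaults 5 and 119,
#'   i.e. calls as short as five residues and keeps candidates under 120).
#' @param host Optional neighborhood/host identifier carried into the output.
#' @return A data.frame of candidates: `orf_id`, `aa_sequence`, `length_aa`,
#'   `frame` (+1..+3 forward, -1..-3 reverse), `start`, `end`, `strand`,
#'   `start_codon`, `score`, `host_neighborhood`.
#' @export
find_short_orfs <- function(dna, span = NULL, min_aa = 5L, max_aa = 119L,
                            host = NA_character_) {
  stopifnot(min_aa >= 1L, max_aa >= min_aa)
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) stop("sequence contains characters outside {A,C,G,T,N}")
  if (is.null(span)) span <- c(1L, nchar(dna))
  stopifnot(span[1] >= 1L, span[2] <= nchar(dna), span[1] <= span[2])
  sub <- substring(dna, span[1], span[2])
  L <- nchar(sub)
  res <- list()

  fwd <- .scan_frames(sub, min_aa, max_aa)
  if (!is.null(fwd)) {
    fwd$strand <- "+"
    fwd$frame <- fwd$frame0 + 1L
    fwd$start <- span[1] + fwd$scan_start - 1L
    fwd$end <- span[1] + fwd$scan_end - 1L
    res$fwd <- fwd
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  rev <- .scan_frames(rc, min_aa, max_aa)
  if (!is.null(rev)) {
    rev$strand <- "-"
    rev$frame <- -(rev$frame0 + 1L)
    # map reverse-scan coords back to forward strand
    rev$start <- span[1] + (L - rev$scan_end + 1L) - 1L
    rev$end <- span[1] + (L - rev$scan_start + 1L) - 1L
    res$rev <- rev
  }
  if (!length(res))
    return(data.frame(orf_id = character(), aa_sequence = character(),
                      length_aa = integer(), frame = integer(),
                      start = integer(), end = integer(), strand = character(),
                      start_codon = character(), score = numeric(),
                      host_neighborhood = character(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, res)
  cand$score <- log(cand$length_aa) + .START_BONUS[cand$start_codon]
  cand$orf_id <- sprintf("orf_%d_%d_%s", cand$start, cand$end, cand$strand)
  cand$host_neighborhood <- host
  rownames(cand) <- NULL
  cand[order(cand$start, cand$end, cand$strand),
       c("orf_id", "aa_sequence", "length_aa", "frame", "start", "end",
         "strand", "start_codon", "score", "host_neighborhood")]
}

#' Dereplicate ORF candidates sharing a stop codon
#'
#' Among candidates with the same stop codon position and frame (nested
#' alternative starts), only the highest-scoring one survives; the score is
#' `ln(length_aa)` plus a start-codon bonus (ATG 0.5, GTG 0.25, TTG 0).
#' Ties keep the longest candidate, then the smallest start coordinate.
#' This is a transparent stand-in for dereplication by gene-caller score.
#'
#' @param cands Candidate data.frame from [find_short_orfs()].
#' @return The surviving subset, original column order preserved.
#' @export
score_and_dereplicate <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  stop_pos <- ifelse(cands$strand == "+", cands$end, cands$start)
  key <- paste(cands$strand, cands$frame, stop_pos)
  ord <- order(key, -cands$score, -cands$length_aa, cands$start)
  cands <- cands[ord, , drop = FALSE]
  out <- cands[!duplicated(paste(cands$strand, cands$frame, stop_pos[ord])), ,
               drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove RRE-like candidates from the precursor pool
#'
#' Candidates matching the query list of RRE-containing proteins — by id, by
#' exact sequence identity to an excluded protein, or by appearing in a
#' profile-match exclusion table — are removed so that RRE domains do not
#' enter precursor-peptide analysis.
#'
#' @param cands Candidate data.frame.
#' @param exclusion_ids Character vector of excluded ids.
#' @param exclusion_seqs Optional named character vector of excluded protein
#'   sequences (exact amino-acid matches are removed).
#' @param exclusion_table Optional path to a TSV whose first column holds
#'   ORF ids matching RRE profiles.
#' @return The filtered candidate data.frame.
#' @export
exclude_rre_like <- function(cands, exclusion_ids = character(),
                             exclusion_seqs = NULL, exclusion_table = NULL) {
  ids <- as.character(exclusion_ids)
  if (!is.null(exclusion_table)) {
    tab <- utils::read.table(exclusion_table, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 1L || !is.character(tab[[1L]]))
      stop("malformed exclusion table: ", exclusion_table)
    ids <- c(ids, tab[[1L]])
  }
  drop <- cands$orf_id %in% ids
  if (!is.null(exclusion_seqs))
    drop <- drop | cands$aa_sequence %in% as.character(exclusion_seqs)
  out <- cands[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harvest precursor candidates for one neighborhood
#'
#' Convenience wrapper: find ORFs in the neighborhood span, dereplicate,
#' and drop RRE-like sequences.
#'
#' @param nb A `neighborhood` from [extract_window()].
#' @param dna Contig nucleotide sequence.
#' @param exclusion_ids,exclusion_seqs Passed to [exclude_rre_like()].
#' @inheritParams find_short_orfs
#' @return The `neighborhood` with its `candidates` slot filled.
#' @export
harvest_neighborhood <- function(nb, dna, min_aa = 5L, max_aa = 119L,
                                 exclusion_ids = character(),
                                 exclusion_seqs = NULL) {
  cands <- find_short_orfs(dna, span = nb$span, min_aa = min_aa,
                           max_aa = max_aa, host = nb$anchor_id)
  cands <- score_and_dereplicate(cands)
  if (nrow(cands))  # contig-scoped ids so candidates join across genomes
    cands$orf_id <- sprintf("%s_%d_%d_%s", nb$contig_id, cands$start,
                            cands$end, cands$strand)
  cands <- exclude_rre_like(cands, exclusion_ids, exclusion_seqs)
  nb$candidates <- cands
  nb
}
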