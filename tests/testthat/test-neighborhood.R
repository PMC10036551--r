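# small genome fixture written in code: one contig, three annotated CDS
write_genome_fixture <- function(dir = tempfile()) {
  dir.create(dir)
  seq <- paste(rep("ACGT", 300), collapse = "")  # 1200 nt
  fasta <- file.path(dir, "g.fna")
  writeLines(c(">ctg1 test contig", seq), fasta)
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg1\ttest\tCDS\t501\t700\t.\t+\t0\tID=geneB",
    "ctg1\ttest\tCDS\t101\t300\t.\t+\t0\tID=geneA",
    "ctg1\ttest\tCDS\t801\t1000\t.\t-\t0\tID=geneC"), gff)
  list(dir = dir, fasta = fasta, gff = gff, seq = seq)
}

test_that("load_genome returns genes sorted by coordinate and checks contigs", {
  fx <- write_genome_fixture()
  g <- load_genome(fx$gff, fx$fasta)
  expect_named(g, "ctg1")
  expect_equal(g$ctg1$genes$gene_id, c("geneA", "geneB", "geneC"))
  expect_equal(g$ctg1$genes$start, c(101L, 501L, 801L))
  expect_equal(nchar(g$ctg1$sequence), 1200L)

  bad <- file.path(fx$dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "ctgMISSING\ttest\tCDS\t1\t30\t.\t+\t0\tID=x"), bad)
  expect_error(load_genome(bad, fx$fasta), "absent from FASTA")

  empty <- file.path(fx$dir, "empty.gff3")
  writeLines("##gff-version 3", empty)
  g0 <- load_genome(empty, fx$fasta)
  expect_named(g0, "ctg1")
  expect_equal(nrow(g0$ctg1$genes), 0L)
})

test_that("extract_window obeys index distance and contig-end truncation", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), contig_id = "c",
                      start = seq(1, by = 100, length.out = 20),
                      end = seq(80, by = 100, length.out = 20),
                      strand = "+", product = NA, stringsAsFactors = FALSE)
  nb <- extract_window(genes, "g11", k = 8)        # anchor index 11
  expect_equal(nrow(nb$genes), 17L)
  expect_equal(nb$genes$gene_id[1], "g03")
  expect_equal(nb$span, c(genes$start[3], genes$end[19]))

  nb0 <- extract_window(genes, "g01", k = 8)
  expect_equal(nrow(nb0$genes), 9L)
  expect_equal(extract_window(genes, "g05", k = 0)$genes$gene_id, "g05")
  expect_error(extract_window(genes, "nope"), "not found")
})

test_that("window membership is symmetric", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:15), contig_id = "c",
                      start = seq(1, by = 50, length.out = 15),
                      end = seq(30, by = 50, length.out = 15),
                      strand = "+", product = NA, stringsAsFactors = FALSE)
  for (k in c(0, 3, 8)) {
    for (a in c("g01", "g07", "g15")) {
      wa <- extract_window(genes, a, k)$genes$gene_id
      for (b in genes$gene_id) {
        wb <- extract_window(genes, b, k)$genes$gene_id
        expect_equal(b %in% wa, a %in% wb)
      }
    }
  }
})

test_that("find_short_orfs translates fixtures on both strands (table 11)", {
  cands <- find_short_orfs("ATGGCTGCTGCTGCTTAA")
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$aa_sequence, "MAAAA")
  expect_equal(cands$length_aa, 5L)
  expect_equal(cands$frame, 1L)
  expect_equal(c(cands$start, cands$end), c(1L, 18L))

  expect_equal(nrow(find_short_orfs("CCCCCCCCCCCCCCCCCC")), 0L)

  # same ORF embedded reverse-complemented in a longer sequence
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGCTGCTGCTGCTTAA")))
  seq <- paste0("CCCCC", rc, "CCCCC")
  cands <- find_short_orfs(seq)
  hit <- cands[cands$aa_sequence == "MAAAA", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "-")
  expect_equal(c(hit$start, hit$end), c(6L, 23L))

  # GTG and TTG starts render as M
  expect_equal(find_short_orfs("GTGGCTGCTGCTGCTTAA")$aa_sequence, "MAAAA")
  expect_equal(find_short_orfs("TTGGCTGCTGCTGCTTAA")$start_codon, "TTG")

  expect_error(find_short_orfs("ATGXCT"), "outside")
  expect_warning(out <- find_short_orfs("ATGGCTGCTGNTGCTTAA"), "N")
  expect_equal(nrow(out), 0L)
})

test_that("ORF candidates round-trip from coordinates to peptide", {
  set.seed(21)
  gc11 <- Biostrings::getGeneticCode("11")
  for (rep in 1:15) {
    dna <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
    cands <- find_short_orfs(dna, min_aa = 5, max_aa = 119)
    for (i in seq_len(nrow(cands))) {
      sub <- substring(dna, cands$start[i], cands$end[i])
      expect_equal(nchar(sub), 3L * (cands$length_aa[i] + 1L))
      if (cands$strand[i] == "-")
        sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
      codons <- substring(sub, seq(1, nchar(sub), 3), seq(3, nchar(sub), 3))
      expect_true(gc11[codons[length(codons)]] == "*")
      pep <- paste(c("M", gc11[codons[-c(1, length(codons))]]), collapse = "")
      expect_equal(pep, cands$aa_sequence[i])
    }
  }
})

test_that("dereplication keeps one ORF per stop/frame by score", {
  # nested starts sharing a stop: lengths 12 and 5, both ATG
  dna <- paste0("ATGGCT", "ATGGCTGCTGCTGCT",
                paste(rep("GCT", 6), collapse = ""), "TAA")
  cands <- find_short_orfs(dna)
  shared <- cands[cands$strand == "+" & cands$end == nchar(dna), ]
  expect_gte(nrow(shared), 2L)
  kept <- score_and_dereplicate(cands)
  kept_shared <- kept[kept$strand == "+" & kept$end == nchar(dna), ]
  expect_equal(nrow(kept_shared), 1L)
  expect_equal(kept_shared$length_aa, max(shared$length_aa))

  # no two survivors share (stop, frame); ORFs in different frames coexist
  set.seed(22)
  for (rep in 1:10) {
    dna <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
    kept <- score_and_dereplicate(find_short_orfs(dna))
    stop_pos <- ifelse(kept$strand == "+", kept$end, kept$start)
    expect_equal(anyDuplicated(paste(kept$strand, kept$frame, stop_pos)), 0L)
  }
})

test_that("RRE-like candidates are excluded by id, sequence, or table", {
  cands <- data.frame(orf_id = c("o1", "o2", "o3"),
                      aa_sequence = c("MAAAA", "MVVVV", "MLLLL"),
                      stringsAsFactors = FALSE)
  expect_equal(exclude_rre_like(cands, exclusion_ids = "o2")$orf_id,
               c("o1", "o3"))
  expect_equal(exclude_rre_like(cands), cands)
  expect_equal(exclude_rre_like(cands, exclusion_seqs = c(rre1 = "MLLLL"))$orf_id,
               c("o1", "o2"))
  tab <- tempfile(); writeLines("o1\tRRE_profile\t1e-10", tab)
  expect_equal(exclude_rre_like(cands, exclusion_table = tab)$orf_id,
               c("o2", "o3"))
})
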