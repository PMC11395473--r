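test_that("FASTA reading normalizes case and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1", "acgt"), fa)
  got <- read_genome_fasta(fa)
  expect_equal(got$seq_id, "chr1")
  expect_equal(got$seq, "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_genome_fasta(fa), "duplicate")

  writeLines(c(">a", "ACXT"), fa)
  expect_error(read_genome_fasta(fa), "position 3")
})

test_that("BED and GFF3 TSS conventions normalize to the same 1-based site", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tg1\t0\t+", "chr1\t0\t1000\tg2\t0\t-"), bed)
  got <- read_tss(bed)
  expect_equal(got$tss[got$gene_id == "g1"], 1000L)
  expect_equal(got$strand[got$gene_id == "g1"], "+")
  expect_equal(got$tss[got$gene_id == "g2"], 1000L)
  expect_equal(got$strand[got$gene_id == "g2"], "-")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1000\t2000\t.\t+\t.\tID=g1"), gff)
  expect_equal(read_tss(gff)$tss, 1000L)

  writeLines("chr1\t999\t2000\tg1\t0\t.", bed)
  expect_error(read_tss(bed), "strand")
})

test_that("promoter extraction has exact coordinate semantics on both strands", {
  genome <- tibble::tibble(seq_id = "c1", seq = strrep("A", 10000))
  tss <- tibble::tibble(gene_id = "g", seq_id = "c1", strand = "+", tss = 6000L)
  w <- extract_promoters(genome, tss)
  expect_equal(w$upstream_len, 5000L)
  expect_equal(w$downstream_len, 1000L)
  expect_equal(nchar(w$seq), 6000L)
  expect_false(w$truncated)

  # truncation at the contig start reduces upstream_len, never pads
  tss$tss <- 1000L
  w <- suppressMessages(extract_promoters(genome, tss))
  expect_equal(w$upstream_len, 999L)
  expect_equal(nchar(w$seq), 1999L)
  expect_true(w$truncated)

  # minus strand: reverse complement, TSS reads at relative +1
  genome <- tibble::tibble(seq_id = "c1", seq = "AAACGTTGCA")
  tss <- tibble::tibble(gene_id = "g", seq_id = "c1", strand = "-", tss = 4L)
  w <- extract_promoters(genome, tss, upstream = 3, downstream = 1)
  # absolute span 4..7 = "CGTT", reverse complement "AACG"
  expect_equal(w$seq, "AACG")
  expect_equal(w$upstream_len, 3L)
  expect_equal(w$downstream_len, 1L)

  tss$tss <- 99L
  expect_error(extract_promoters(genome, tss), "off the sequence")
})

test_that("window relative coordinates round-trip to absolute positions", {
  withr::local_seed(42)
  for (rep in 1:20) {
    len <- sample(50:200, 1)
    contig <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    genome <- tibble::tibble(seq_id = "c", seq = contig)
    strand <- sample(c("+", "-"), 1)
    pos <- sample(seq_len(len), 1)
    up <- sample(0:30, 1); down <- sample(1:20, 1)
    tss <- tibble::tibble(gene_id = "g", seq_id = "c", strand = strand, tss = pos)
    w <- suppressMessages(extract_promoters(genome, tss, up, down))
    expect_equal(nchar(w$seq), w$upstream_len + w$downstream_len)
    # every window position maps to the absolute base it came from
    for (j in seq_len(nchar(w$seq))) {
      rel <- ifelse(j <= w$upstream_len, j - w$upstream_len - 1L, j - w$upstream_len)
      abs_pos <- if (strand == "+") pos + ifelse(rel < 0, rel, rel - 1L)
                 else pos - ifelse(rel < 0, rel, rel - 1L)
      base <- substr(contig, abs_pos, abs_pos)
      if (strand == "-") base <- chartr("ACGT", "TGCA", base)
      expect_equal(substr(w$seq, j, j), base)
    }
  }
})

test_that("JASPAR PFM parsing is row-order invariant and validated", {
  jas <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1\tTF1", "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 0 ]"), jas)
  got <- read_jaspar_pfm(jas)
  expect_equal(got$length, 2L)
  expect_equal(got$consensus, "AC")

  # same matrix with rows given T,G,C,A
  writeLines(c(">M1\tTF1", "T [ 0 0 ]", "G [ 0 0 ]", "C [ 0 4 ]", "A [ 4 0 ]"), jas)
  expect_equal(read_jaspar_pfm(jas)$counts[[1]], got$counts[[1]])

  writeLines(c(">M1\tTF1", "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]"), jas)
  expect_error(read_jaspar_pfm(jas), "one row per base")

  writeLines(c(">M1\tTF1", "A [ 4 0 1 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 0 ]"), jas)
  expect_error(read_jaspar_pfm(jas), "ragged")
})

test_that("JASPAR write/read round-trips matrices exactly", {
  pfms <- dplyr::bind_rows(
    simulate_pfm(8, 0.9, matrix_id = "MA0001.1", tf_name = "alpha", seed = 1),
    simulate_pfm_dirichlet(5, seed = 2, matrix_id = "MA0002.1", tf_name = "beta")
  )
  jas <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar_pfm(pfms, jas)
  back <- read_jaspar_pfm(jas)
  expect_equal(back$matrix_id, pfms$matrix_id)
  expect_equal(back$tf_name, pfms$tf_name)
  expect_equal(back$counts, pfms$counts)
})

test_that("promoter FASTA headers preserve the relative coordinate system", {
  prom <- simulate_promoters(
    c("g1", "g2"), simulate_pfm(6, 0.9, seed = 1, matrix_id = "M"),
    tibble::tibble(matrix_id = "M", gene_id = "g1", n_sites = 1),
    upstream = 40, downstream = 10, seed = 9
  )$promoters
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_fasta(prom, fa)
  back <- read_promoter_fasta(fa)
  expect_equal(back$gene_id, prom$gene_id)
  expect_equal(back$upstream_len, prom$upstream_len)
  expect_equal(back$downstream_len, prom$downstream_len)
  expect_equal(back$seq, prom$seq)
})
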