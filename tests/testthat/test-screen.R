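mini_hits <- function(df) {
  # build a minimal hit table from (tf, gene) pairs
  rel <- if ("rel" %in% names(df)) df$rel else rep(-100L, nrow(df))
  tibble::tibble(
    matrix_id = paste0("M_", df$tf), tf_name = df$tf, gene_id = df$gene,
    relative_start = rel, relative_end = rel + 5L,
    strand = "+", score_bits = 10, p_value = 1e-6,
    region = classify_region(rel)
  )
}

test_that("the intersection rule requires a hit in every group gene", {
  groups <- tibble::tibble(hormone = "SA", category = "biosynthesis",
                           gene_id = c("g1", "g2"))
  hits <- mini_hits(tibble::tibble(tf = c("TF1", "TF1", "TF2"),
                                   gene = c("g1", "g2", "g1")))
  calls <- screen_masters(hits, groups)
  expect_equal(unique(calls$tf), "TF1")

  # a TF hitting all genes of two groups appears once per group
  groups2 <- dplyr::bind_rows(
    groups,
    tibble::tibble(hormone = "JA", category = "signaling", gene_id = c("g1", "g3"))
  )
  hits2 <- mini_hits(tibble::tibble(tf = "TF1", gene = c("g1", "g2", "g3")))
  calls2 <- screen_masters(hits2, groups2)
  expect_equal(nrow(calls2), 2L)
  expect_setequal(paste(calls2$hormone, calls2$category),
                  c("SA biosynthesis", "JA signaling"))
})

test_that("min_fraction relaxes the intersection rule monotonically", {
  groups <- tibble::tibble(hormone = "SA", category = "biosynthesis",
                           gene_id = paste0("g", 1:4))
  hits <- mini_hits(tibble::tibble(tf = "TF1", gene = paste0("g", 1:3)))
  expect_equal(nrow(screen_masters(hits, groups)), 0L)
  relaxed <- screen_masters(hits, groups, min_fraction = 0.75)
  expect_equal(relaxed$tf, "TF1")
  expect_equal(relaxed$fraction, 0.75)
})

test_that("screening equals a brute-force membership check on random tables", {
  withr::local_seed(51)
  for (rep in 1:8) {
    tfs <- paste0("TF", 1:5)
    genes <- paste0("g", 1:6)
    pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.55, ]
    # some TFs hit a gene several times; duplicates must not matter
    pairs <- rbind(pairs, pairs[sample.int(nrow(pairs), 5, replace = TRUE), ])
    hits <- mini_hits(tibble::as_tibble(pairs))
    groups <- tibble::tibble(
      hormone = rep(c("SA", "JA"), each = 3),
      category = rep(c("biosynthesis", "signaling"), 3),
      gene_id = sample(genes, 6)
    )
    frac <- sample(c(1, 0.5), 1)
    got <- sort_calls(screen_masters(hits, groups, min_fraction = frac))
    want <- brute_force_masters(hits, groups, min_fraction = frac)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("biosynthesis/signaling overlap requires mastering both categories", {
  calls <- tibble::tibble(
    tf = c("A", "A", "B", "C"),
    hormone = c("SA", "JA", "SA", "ET"),
    category = c("biosynthesis", "signaling", "biosynthesis", "signaling"),
    n_genes = 2L, n_genes_hit = 2L, fraction = 1
  )
  expect_equal(overlap_masters(calls), "A")
  by_h <- masters_by_hormone(calls, "biosynthesis")
  expect_equal(by_h$union, c("A", "B"))
  expect_equal(by_h$per_hormone$SA, c("A", "B"))
})

test_that("region counts conserve totals and match an independent recount", {
  hits <- mini_hits(tibble::tibble(
    tf = c("TF1", "TF1", "TF1"), gene = "g1", rel = c(-50L, -10L, 3L)
  ))
  rc <- region_counts(hits)
  expect_equal(rc$upstream, 2L)
  expect_equal(rc$downstream, 1L)
  expect_equal(rc$total, 3L)
  expect_equal(hit_totals(hits)$total_hits, 3L)

  # independent recount straight off the TSV
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, tsv, sidecar = FALSE)
  raw <- utils::read.delim(tsv)
  expect_equal(sum(raw$region == "upstream"), rc$upstream)
  expect_equal(unname(table(raw$gene_id)["g1"]),
               hit_totals(hits)$total_hits, ignore_attr = TRUE)

  # degenerate: no hits at all
  empty <- hits[0, ]
  expect_equal(nrow(screen_masters(empty, tibble::tibble(
    hormone = "SA", category = "biosynthesis", gene_id = "g1"
  ))), 0L)
  expect_equal(nrow(hit_totals(empty)), 0L)
})

test_that("removing hits or adding group genes never adds a master", {
  withr::local_seed(61)
  tfs <- paste0("TF", 1:4); genes <- paste0("g", 1:5)
  pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < 0.7, ]
  hits <- mini_hits(tibble::as_tibble(pairs))
  groups <- tibble::tibble(hormone = "SA", category = "biosynthesis",
                           gene_id = genes[1:3])
  base_calls <- screen_masters(hits, groups)
  # drop random hit rows
  fewer <- hits[-sample.int(nrow(hits), 3), ]
  fewer_calls <- screen_masters(fewer, groups)
  expect_true(all(fewer_calls$tf %in% base_calls$tf))
  # grow the group
  bigger <- dplyr::bind_rows(groups, tibble::tibble(
    hormone = "SA", category = "biosynthesis", gene_id = "g5"
  ))
  bigger_calls <- screen_masters(hits, bigger)
  expect_true(all(bigger_calls$tf %in% base_calls$tf))
})

test_that("group YAML round-trips and validates", {
  groups <- tibble::tibble(
    hormone = rep(c("SA", "JA"), each = 2),
    category = rep(c("biosynthesis", "signaling"), 2),
    gene_id = c("a", "b", "c", "d")
  )
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_groups(groups, yml)
  expect_equal(as.data.frame(read_groups(yml)), as.data.frame(groups))

  prom <- toy_promoter("ACGT", gene_id = "a")
  expect_error(validate_groups(groups, prom), "without a scanned promoter")

  shipped <- system.file("extdata", "athaliana_groups.yaml", package = "masterscan")
  sh <- read_groups(shipped)
  expect_equal(sum(sh$category == "biosynthesis"), 32L)
  expect_equal(sum(sh$category == "signaling"), 9L)
})
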