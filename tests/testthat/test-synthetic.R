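test_that("background composition matches the requested distribution", {
  bg <- background_model(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  sim <- simulate_promoters(paste0("g", 1:20), simulate_pfm(6, 0.9, seed = 1, matrix_id = "M"),
                            plan = tibble::tibble(matrix_id = character(),
                                                  gene_id = character(),
                                                  n_sites = integer()),
                            upstream = 4000, downstream = 1000,
                            background = bg, seed = 71)
  expect_equal(nrow(sim$sites), 0L)
  n <- 20 * 5000
  freq <- table(factor(strsplit(paste(sim$promoters$seq, collapse = ""), "")[[1]],
                       levels = c("A", "C", "G", "T"))) / n
  for (b in names(bg)) {
    se <- sqrt(bg[[b]] * (1 - bg[[b]]) / n)
    expect_lt(abs(freq[[b]] - bg[[b]]), 3 * se)
  }
})

test_that("a deterministic PFM plants its consensus at the recorded offset", {
  pfm <- consensus_pfm("ACGTAC")
  sim <- simulate_promoters("g1", pfm, tibble::tibble(
    matrix_id = "CONS", gene_id = "g1", n_sites = 1
  ), upstream = 80, downstream = 20, seed = 5)
  s <- sim$sites
  expect_equal(s$instance, "ACGTAC")
  pos <- ifelse(s$relative_start < 0, s$relative_start + 81L, s$relative_start + 80L)
  expect_equal(substr(sim$promoters$seq, pos, pos + 5L), "ACGTAC")
})

test_that("promoter simulation is deterministic under a seed", {
  pfm <- simulate_pfm(8, 0.9, seed = 2, matrix_id = "M")
  plan <- tibble::tibble(matrix_id = "M", gene_id = "g1", n_sites = 2)
  a <- simulate_promoters("g1", pfm, plan, upstream = 200, downstream = 50, seed = 77)
  b <- simulate_promoters("g1", pfm, plan, upstream = 200, downstream = 50, seed = 77)
  c <- simulate_promoters("g1", pfm, plan, upstream = 200, downstream = 50, seed = 78)
  expect_identical(a, b)
  expect_false(identical(a$promoters$seq, c$promoters$seq))
  expect_error(simulate_promoters("g1", pfm, plan, upstream = 3, downstream = 2, seed = 1),
               "longer than the window")
})

test_that("planted negative-binomial folds are recovered in CPM", {
  ratios <- sapply(1:50, function(s) {
    cnt <- simulate_counts(paste0("g", 1:80),
                           means = stats::rlnorm(80, log(1000), 0.5),
                           folds = c(3.25, rep(1, 79)), dispersion = 0.02,
                           seed = 100 + s)
    cpm <- compute_cpm(cnt$counts)
    cpm$treated[1] / cpm$control[1]
  })
  expect_lt(abs(stats::median(ratios) - 3.25) / 3.25, 0.05)
})

test_that("zero dispersion approaches Poisson counts", {
  cnt <- simulate_counts(paste0("g", 1:2000), means = 200, folds = 1,
                         dispersion = 0, lib_control = 4e5, lib_treated = 4e5,
                         seed = 91)
  vm <- stats::var(cnt$counts$control) / mean(cnt$counts$control)
  expect_lt(abs(vm - 1), 0.15)
  # and a clearly overdispersed table is not Poisson
  cnt2 <- simulate_counts(paste0("g", 1:2000), means = 200, folds = 1,
                          dispersion = 0.5, lib_control = 4e5, lib_treated = 4e5,
                          seed = 92)
  expect_gt(stats::var(cnt2$counts$control) / mean(cnt2$counts$control), 5)
})

test_that("null count tables are exchangeable between conditions", {
  # planted fold 1 everywhere: treated/control CPM ratios should straddle 1
  reject <- sapply(1:40, function(s) {
    cnt <- simulate_counts(paste0("g", 1:100), means = 500, folds = 1,
                           dispersion = 0.05, seed = 300 + s)
    cpm <- compute_cpm(cnt$counts)
    suppressWarnings(stats::ks.test(cpm$control, cpm$treated)$p.value < 0.01)
  })
  expect_lte(mean(reject), 0.05)
})

test_that("simulated PFM sets keep motifs mutually distinguishable", {
  pfms <- simulate_pfm_set(6, length = 10, sharpness = 0.95, seed = 41)
  cons <- lapply(strsplit(pfms$consensus, ""), match, c("A", "C", "G", "T"))
  for (i in 1:5) for (j in (i + 1):6) {
    best <- 0
    for (sh in -9:9) {
      ia <- max(1, 1 + sh):min(10, 10 + sh)
      best <- max(best, sum(cons[[i]][ia] == cons[[j]][ia - sh]))
    }
    expect_lte(best, 5)
  }
})

test_that("fixture files are byte-identical across runs at a fixed seed", {
  cfg <- fixture_config(seed = 404, upstream = 1000, downstream = 200,
                             sites_per_gene = 2L)
  cfg$n_background_genes <- 20L
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(build_fixture(cfg), d1)
  write_fixture(build_fixture(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the promoters
  cfg2 <- cfg; cfg2$seed <- 405L
  d3 <- withr::local_tempdir()
  write_fixture(build_fixture(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "promoters.fasta"))),
                         unname(tools::md5sum(file.path(d3, "promoters.fasta")))))
})

test_that("the bundled fixture encodes the designed cardinalities", {
  fx <- get_fixture()
  expect_equal(nrow(fx$promoters), 41L)  # 32 biosynthesis + 9 signaling genes
  expect_equal(sum(fx$groups$category == "biosynthesis"), 32L)
  expect_equal(sum(fx$groups$category == "signaling"), 9L)
  truth_bio <- fx$truth$masters[fx$truth$masters$category == "biosynthesis", ]
  expect_equal(length(unique(truth_bio$tf)), 14L)
  expect_equal(unname(table(truth_bio$hormone)[c("SA", "JA", "ABA", "ET")]),
               c(4L, 9L, 5L, 10L), ignore_attr = TRUE)
  expect_equal(length(fx$truth$overlap), 7L)
  # planted DE: the lead factor carries the 3.25x fold
  lead <- fx$truth$de[fx$truth$de$gene_id == "synDOF1", ]
  expect_equal(lead$fold, 3.25)
})
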