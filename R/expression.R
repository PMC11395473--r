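#' Read a gene x sample count table
#'
#' TSV with a `gene_id` column followed by one integer column per sample.
#'
#' @param path TSV path.
#' @return Tibble with `gene_id` plus sample columns.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(gene_id = "c", .default = "d"))
  if (!"gene_id" %in% names(counts)) abort("count table needs a gene_id column")
  validate_counts(counts)
  counts
}

validate_counts <- function(counts) {
  mat <- count_matrix(counts)
  if (any(mat < 0)) abort("counts must be non-negative")
  zero <- colSums(mat) == 0
  if (any(zero)) {
    abort(paste0("zero library size for sample: ", colnames(mat)[zero][[1L]]))
  }
  invisible(counts)
}

count_matrix <- function(counts) {
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(mat) <- counts$gene_id
  mat
}

#' Counts per million
#'
#' `cpm(g, s) = counts(g, s) / library_size(s) * 1e6` with the library size
#' being the column sum, so each sample's CPM column sums to one million.
#'
#' @param counts Count tibble (`gene_id` + sample columns) or numeric matrix.
#' @return Same shape as the input, in CPM units.
#' @export
compute_cpm <- function(counts) {
  tab <- is.data.frame(counts)
  mat <- if (tab) count_matrix(counts) else counts
  lib <- colSums(mat)
  if (any(lib <= 0)) {
    abort(paste0("zero library size for sample: ", colnames(mat)[lib <= 0][[1L]]))
  }
  cpm <- sweep(mat, 2L, lib, "/") * 1e6
  if (!tab) return(cpm)
  out <- as_tibble(cpm)
  out$gene_id <- counts$gene_id
  relocate(out, "gene_id")
}

#' Percent change in CPM between conditions
#'
#' The field's reporting convention: `(treated - control) / control * 100`,
#' so a 3.25-fold CPM ratio is reported as a +225% increase. Undefined when
#' the control CPM is 0 (`NA` with a warning; such records are excluded from
#' percent reporting).
#'
#' @param cpm_control,cpm_treated CPM values.
#' @return Percent change(s).
#' @export
percent_change <- function(cpm_control, cpm_treated) {
  out <- ifelse(cpm_control > 0, (cpm_treated - cpm_control) / cpm_control * 100, NA_real_)
  if (anyNA(out)) warn("percent_change undefined where control CPM is 0; returned NA")
  out
}

#' Pairwise differential expression by the simulated-replicate M-D procedure
#'
#' For a one-control vs one-treated design (no replicates), each gene gets
#' `M = log2((cpm_t + k)/(cpm_c + k))` and `D = |cpm_t - cpm_c|`. A noise
#' distribution of (M*, D*) pairs is built by drawing multinomial technical
#' replicates of each library at its observed gene proportions and comparing
#' replicate pairs within the same condition, pooled across genes. The DE
#' probability of a gene is the fraction of noise pairs strictly less extreme
#' in both coordinates (`|M*| < |M|` and `D* < D`); genes reach an `up`/`down`
#' call by the sign of M when that probability is at least `q`.
#'
#' @param counts Count tibble or matrix with exactly the two columns named by
#'   `control` and `treated`.
#' @param control,treated Sample (column) names.
#' @param n_sim Target number of pooled noise points (default 5000).
#' @param n_rep Simulated technical replicates per condition per round
#'   (default 5; each round contributes `2 * choose(n_rep, 2)` replicate
#'   pairs).
#' @param k Pseudo-CPM added inside the log ratio (default 0.5).
#' @param q Probability threshold for an up/down call (default 0.8).
#' @param seed Optional integer seed; the simulation is fully reproducible
#'   given it.
#' @return A tibble of class `de_test`: `gene_id`, `cpm_control`,
#'   `cpm_treated`, `percent_change`, `M`, `D`, `de_probability`, `call`.
#' @export
de_test <- function(counts, control = "control", treated = "treated",
                    n_sim = 5000, n_rep = 5, k = 0.5, q = 0.8, seed = NULL) {
  mat <- if (is.data.frame(counts)) count_matrix(counts) else counts
  for (nm in c(control, treated)) {
    if (!nm %in% colnames(mat)) abort(paste0("no sample column named '", nm, "'"))
  }
  if (n_sim < 1000) abort("n_sim must be >= 1000")
  if (n_rep < 2) abort("n_rep must be >= 2")
  x_c <- mat[, control]
  x_t <- mat[, treated]
  lib_c <- sum(x_c)
  lib_t <- sum(x_t)
  if (lib_c <= 0 || lib_t <= 0) abort("zero library size")
  cpm_c <- x_c / lib_c * 1e6
  cpm_t <- x_t / lib_t * 1e6
  M <- log2((cpm_t + k) / (cpm_c + k))
  D <- abs(cpm_t - cpm_c)

  n_genes <- length(x_c)
  pairs_per_round <- 2L * choose(n_rep, 2L)
  rounds <- max(1L, ceiling(n_sim / (pairs_per_round * n_genes)))
  noise <- with_seed_if(seed, {
    pts <- list()
    for (r in seq_len(rounds)) {
      for (cond in list(x_c, x_t)) {
        libsize <- sum(cond)
        reps <- rmultinom(n_rep, size = libsize, prob = cond / libsize)
        cpm_reps <- reps / libsize * 1e6
        for (i in seq_len(n_rep - 1L)) {
          for (j in seq(i + 1L, n_rep)) {
            pts[[length(pts) + 1L]] <- cbind(
              M = log2((cpm_reps[, i] + k) / (cpm_reps[, j] + k)),
              D = abs(cpm_reps[, i] - cpm_reps[, j])
            )
          }
        }
      }
    }
    do.call(rbind, pts)
  })
  if (nrow(noise) > n_sim) {
    # deterministic thinning keeps exactly n_sim noise points
    noise <- noise[round(seq(1L, nrow(noise), length.out = n_sim)), , drop = FALSE]
  }
  nm_abs <- abs(noise[, "M"])
  nd <- noise[, "D"]
  ord <- order(nm_abs)
  nm_sorted <- nm_abs[ord]
  nd_sorted <- nd[ord]
  de_probability <- vapply(seq_len(n_genes), function(g) {
    upto <- findInterval(abs(M[[g]]), nm_sorted, left.open = TRUE)
    if (upto == 0L) return(0)
    mean_lt <- sum(nd_sorted[seq_len(upto)] < D[[g]])
    mean_lt / length(nd)
  }, numeric(1))
  call <- ifelse(
    de_probability >= q & M != 0,
    ifelse(M > 0, "up", "down"),
    "ns"
  )
  out <- tibble(
    gene_id = rownames(mat) %||% as.character(seq_len(n_genes)),
    cpm_control = unname(cpm_c), cpm_treated = unname(cpm_t),
    percent_change = suppressWarnings(percent_change(cpm_c, cpm_t)),
    M = unname(M), D = unname(D),
    de_probability = de_probability,
    call = unname(call)
  )
  structure(
    out,
    class = c("de_test", class(tibble())),
    de_config = list(n_sim = nrow(noise), n_rep = n_rep, k = k, q = q, seed = seed,
                     control = control, treated = treated,
                     lib_control = lib_c, lib_treated = lib_t)
  )
}

#' Relative expression by the ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_hk,treated) - (Ct_target,control -
#' Ct_hk,control)`; relative expression is `2^(-ddCt)` against the
#' housekeeping gene and the control condition. Records with any missing Ct
#' are skipped with a warning.
#'
#' @param qpcr Tibble with columns `gene_id`, `ct_target_control`,
#'   `ct_target_treated`, `ct_hk_control`, `ct_hk_treated`.
#' @return Input tibble plus `delta_delta_ct` and `relative_expression`.
#' @export
ddct <- function(qpcr) {
  need <- c("gene_id", "ct_target_control", "ct_target_treated",
            "ct_hk_control", "ct_hk_treated")
  miss <- setdiff(need, names(qpcr))
  if (length(miss) > 0L) abort(paste0("qPCR table missing column(s): ", paste(miss, collapse = ", ")))
  complete <- stats::complete.cases(qpcr[need])
  if (any(!complete)) {
    warn(paste0("skipping ", sum(!complete), " qPCR record(s) with missing Ct"))
    qpcr <- qpcr[complete, ]
  }
  qpcr |>
    mutate(
      delta_delta_ct = (.data$ct_target_treated - .data$ct_hk_treated) -
        (.data$ct_target_control - .data$ct_hk_control),
      relative_expression = 2^(-.data$delta_delta_ct)
    )
}

#' Pearson correlation between qPCR relative expression and CPM
#'
#' Validates a sequencing-based expression index against
#' RT-qPCR via the Pearson correlation of the two measures over a gene
#' panel (reads/counts per million are treated as the same per-million
#' index here).
#'
#' @param relative_expression,cpm Equal-length numeric vectors (n >= 3,
#'   finite).
#' @return Pearson r.
#' @export
validation_correlation <- function(relative_expression, cpm) {
  if (length(relative_expression) != length(cpm)) abort("vectors must have equal length")
  if (length(cpm) < 3L) abort("need at least 3 points")
  if (!all(is.finite(relative_expression)) || !all(is.finite(cpm))) {
    abort("values must be finite")
  }
  if (stats::sd(relative_expression) == 0 || stats::sd(cpm) == 0) {
    abort("correlation undefined: zero variance")
  }
  cor(relative_expression, cpm)
}
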