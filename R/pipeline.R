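#' Run the full promoter-scan / master-screen / expression pipeline
#'
#' Orchestrates: load promoters (directly, or extract them from a genome +
#' TSS table), load motifs and pathway groups, scan at the p-value
#' stringency, screen for master regulatory TFs, tally upstream/downstream
#' binding regions, run the CPM / M-D expression analysis when a count table
#' is given, and write a report bundle:
#' `hits.tsv` (+ `.json` sidecar), `masters.tsv`, `summary.tsv`,
#' `overlap.txt`, `expression.tsv`, `report.json`. The report joins each
#' master TF to its expression record (percent change and call), the
#' "master TFs and how they moved" view such screens report.
#'
#' @param promoters Promoter FASTA path (headers
#'   `gene_id|strand|upstream_len|downstream_len`) or a promoter tibble.
#' @param motifs JASPAR PFM path or PFM tibble.
#' @param groups Groups YAML path or tibble.
#' @param counts Optional counts TSV path or tibble (`gene_id`, `control`,
#'   `treated`).
#' @param genome,tss Alternative promoter input: genome FASTA + TSS BED/GFF3
#'   (used when `promoters` is `NULL`).
#' @param outdir Output directory.
#' @param p_threshold,both_strands,pseudocount,scale Scan settings (see
#'   [scan_promoters()]).
#' @param background `NULL` for the promoter-set composition, or an explicit
#'   model.
#' @param by,min_fraction Screening settings (see [screen_masters()]).
#' @param upstream,downstream Window extent when extracting from a genome.
#' @param n_sim,n_rep,k,q Expression settings (see [de_test()]).
#' @param seed Integer seed for the expression noise simulation.
#' @return Invisibly, a list with `hits`, `calls`, `summary`, `expression`,
#'   `report` (and the paths written).
#' @export
run_pipeline <- function(promoters = NULL, motifs, groups, counts = NULL,
                         genome = NULL, tss = NULL,
                         outdir, p_threshold = 1e-4, both_strands = FALSE,
                         pseudocount = 1, scale = 1000L, background = NULL,
                         by = "tf_name", min_fraction = 1,
                         upstream = 5000L, downstream = 1000L,
                         n_sim = 5000, n_rep = 5, k = 0.5, q = 0.8,
                         seed = 1L) {
  # ---- validate & load everything before any compute ----
  input_paths <- list()
  load_or <- function(x, loader, label) {
    if (is.character(x)) {
      if (!file.exists(x)) abort(paste0(label, " file not found: ", x))
      input_paths[[label]] <<- x
      loader(x)
    } else {
      x
    }
  }
  if (is.null(promoters)) {
    if (is.null(genome) || is.null(tss)) {
      abort("provide either a promoter FASTA/tibble or a genome + TSS table")
    }
    genome_tbl <- load_or(genome, read_genome_fasta, "genome")
    tss_tbl <- load_or(tss, read_tss, "tss")
    promoters <- extract_promoters(genome_tbl, tss_tbl,
                                   upstream = upstream, downstream = downstream)
  } else {
    promoters <- load_or(promoters, read_promoter_fasta, "promoters")
  }
  pfms <- load_or(motifs, read_jaspar_pfm, "motifs")
  groups <- load_or(groups, read_groups, "groups")
  validate_groups(groups, promoters)
  if (!is.null(counts)) counts <- load_or(counts, read_counts, "counts")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # ---- scan ----
  hits <- scan_promoters(promoters, pfms, p_threshold = p_threshold,
                         both_strands = both_strands, background = background,
                         pseudocount = pseudocount, scale = scale)
  inform(paste0("scan: ", nrow(promoters), " promoters x ", nrow(pfms),
                " matrices -> ", nrow(hits), " hits (",
                attr(hits, "scan_config")$skipped_offsets, " offsets skipped)"))
  write_hits(hits, file.path(outdir, "hits.tsv"))

  # ---- screen ----
  calls <- screen_masters(hits, groups, by = by, min_fraction = min_fraction)
  summ <- screen_summary(hits, calls, promoters)
  inform(paste0("screen: ", length(summ$biosynthesis$union),
                " biosynthesis master TF(s), ", length(summ$overlap),
                " also mastering signaling"))
  readr::write_tsv(as_tibble(calls), file.path(outdir, "masters.tsv"))
  readr::write_tsv(
    summ$master_region_counts |>
      left_join(summ$promoter_totals, by = "gene_id") |>
      relocate("gene_id"),
    file.path(outdir, "summary.tsv")
  )
  writeLines(summ$overlap, file.path(outdir, "overlap.txt"))

  # ---- expression ----
  expression <- NULL
  if (!is.null(counts)) {
    expression <- de_test(counts, n_sim = n_sim, n_rep = n_rep, k = k, q = q,
                          seed = seed)
    inform(paste0("express: ", nrow(expression), " genes, ",
                  sum(expression$call != "ns"), " called DE at q >= ", q))
    readr::write_tsv(as_tibble(expression), file.path(outdir, "expression.tsv"))
  }

  # ---- report ----
  master_expr <- tibble(tf = summ$biosynthesis$union)
  if (!is.null(expression)) {
    master_expr <- master_expr |>
      left_join(
        as_tibble(expression) |>
          select(tf = "gene_id", "cpm_control", "cpm_treated",
                 "percent_change", "de_probability", "call"),
        by = "tf"
      )
  }
  groups_of <- as_tibble(calls) |>
    group_by(.data$tf) |>
    summarise(groups = paste(paste0(.data$hormone, ":", .data$category), collapse = ";"),
              .groups = "drop")
  report <- list(
    tool = list(package = "masterscan",
                version = as.character(packageVersion("masterscan"))),
    seed = seed,
    inputs = lapply(input_paths, function(pth) {
      list(path = pth, md5 = unname(tools::md5sum(pth)))
    }),
    scan = attr(hits, "scan_config")[c("p_threshold", "both_strands",
                                       "pseudocount", "scale",
                                       "skipped_offsets")],
    background = as.list(attr(hits, "scan_config")$background),
    n_hits = nrow(hits),
    masters = list(
      biosynthesis = summ$biosynthesis$per_hormone,
      biosynthesis_union = summ$biosynthesis$union,
      signaling = summ$signaling$per_hormone,
      overlap = summ$overlap
    ),
    master_expression = master_expr |> left_join(groups_of, by = "tf")
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(
    hits = hits, calls = calls, summary = summ, expression = expression,
    report = report, outdir = outdir
  ))
}
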