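#' Read a pathway-group configuration
#'
#' Groups are YAML mapping hormone -> category -> gene list, e.g.
#' `SA: {biosynthesis: [ICS1, EDS5], signaling: [NPR1, PR1]}`. Hormones are
#' the four stress phytohormones SA, JA, ABA, ET; categories are
#' `biosynthesis` and `signaling`.
#'
#' @param path YAML file path.
#' @return A tibble with columns `hormone`, `category`, `gene_id`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) abort(paste0("groups file not found: ", path))
  y <- yaml::read_yaml(path)
  rows <- list()
  for (hormone in names(y)) {
    for (category in names(y[[hormone]])) {
      genes <- unlist(y[[hormone]][[category]])
      if (length(genes) == 0L) abort(paste0("empty gene list for ", hormone, "/", category))
      rows[[length(rows) + 1L]] <- tibble(
        hormone = hormone, category = category, gene_id = as.character(genes)
      )
    }
  }
  out <- bind_rows(rows)
  dup <- out |> dplyr::count(.data$hormone, .data$category, .data$gene_id) |> filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate gene '", dup$gene_id[[1L]], "' in group ",
                 dup$hormone[[1L]], "/", dup$category[[1L]]))
  }
  out
}

#' @rdname read_groups
#' @param groups Groups tibble.
#' @export
write_groups <- function(groups, path) {
  y <- list()
  for (h in unique(groups$hormone)) {
    y[[h]] <- list()
    for (cat in unique(groups$category[groups$hormone == h])) {
      y[[h]][[cat]] <- groups$gene_id[groups$hormone == h & groups$category == cat]
    }
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Validate a group configuration against the scanned promoter set
#'
#' Every gene named in a pathway group must have a promoter in the scanned
#' set; a dangling reference is a configuration error raised before any
#' screening.
#'
#' @param groups Groups tibble.
#' @param promoters Promoter tibble.
#' @return `groups`, invisibly.
#' @export
validate_groups <- function(groups, promoters) {
  missing <- setdiff(groups$gene_id, promoters$gene_id)
  if (length(missing) > 0L) {
    abort(paste0("group gene(s) without a scanned promoter: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  invisible(groups)
}

#' Screen motif hits for master regulatory transcription factors
#'
#' A TF is called a master regulator of a pathway group when it has at least
#' one predicted binding site in the promoter of *every* gene of the group
#' (the intersection rule). `min_fraction` relaxes the rule to a fraction of
#' the group's genes (1 = strict intersection). Hits can be aggregated per
#' TF name (default; several matrices for one factor pool their hits) or per
#' matrix.
#'
#' @param hits Hit tibble from [scan_promoters()] (already thresholded).
#' @param groups Groups tibble from [read_groups()].
#' @param by Aggregation unit: `"tf_name"` (default) or `"matrix_id"`.
#' @param min_fraction Minimum fraction of group genes with >= 1 hit
#'   (default 1, the strict intersection).
#' @return A tibble of class `master_screen` with one row per
#'   (tf, hormone, category) satisfied: columns `tf`, `hormone`, `category`,
#'   `n_genes`, `n_genes_hit`, `fraction`.
#' @export
screen_masters <- function(hits, groups, by = c("tf_name", "matrix_id"),
                           min_fraction = 1) {
  by <- match.arg(by)
  if (min_fraction <= 0 || min_fraction > 1) abort("min_fraction must be in (0,1]")
  # a hit table does not record hitless genes, so membership of group genes in
  # the scanned set is validated where the promoter set is in hand
  # (run_pipeline / validate_groups)
  hits <- as_tibble(hits)
  hits$tf <- hits[[by]]
  presence <- hits |>
    distinct(.data$tf, .data$gene_id)
  group_sizes <- groups |>
    dplyr::count(.data$hormone, .data$category, name = "n_genes")
  calls <- groups |>
    inner_join(presence, by = "gene_id", relationship = "many-to-many") |>
    group_by(.data$tf, .data$hormone, .data$category) |>
    summarise(n_genes_hit = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    left_join(group_sizes, by = c("hormone", "category")) |>
    mutate(fraction = .data$n_genes_hit / .data$n_genes) |>
    filter(.data$fraction >= min_fraction) |>
    select("tf", "hormone", "category", "n_genes", "n_genes_hit", "fraction") |>
    arrange(.data$tf, .data$hormone, .data$category)
  structure(
    calls,
    class = c("master_screen", class(tibble())),
    by = by, min_fraction = min_fraction,
    gene_universe = sort(unique(c(hits$gene_id, groups$gene_id)))
  )
}

#' Masters of both biosynthesis and signaling
#'
#' TFs that master at least one biosynthesis group and at least one
#' signaling group (screens of this kind report this overlap alongside the
#' per-hormone lists).
#'
#' @param calls `master_screen` tibble from [screen_masters()].
#' @return Lexicographically sorted character vector of TF identifiers.
#' @export
overlap_masters <- function(calls) {
  bio <- unique(calls$tf[calls$category == "biosynthesis"])
  sig <- unique(calls$tf[calls$category == "signaling"])
  sort(intersect(bio, sig))
}

#' Per-hormone master lists and their union
#'
#' @param calls `master_screen` tibble.
#' @param category Category to tabulate (default `"biosynthesis"`).
#' @return A list with `per_hormone` (named list of TF vectors) and `union`.
#' @export
masters_by_hormone <- function(calls, category = "biosynthesis") {
  calls <- calls[calls$category == category, ]
  hs <- sort(unique(calls$hormone))
  per <- lapply(hs, function(h) sort(unique(calls$tf[calls$hormone == h])))
  names(per) <- hs
  list(per_hormone = per, union = sort(unique(calls$tf)))
}

#' Binding-site accounting for promoters and master TFs
#'
#' `hit_totals()` counts all binding-site hits per promoter (the first
#' summary statistic of a promoter screen: which genes attract the most and
#' fewest predicted sites). `region_counts()` tallies upstream vs downstream sites per
#' TF x gene; upstream + downstream always equals the total.
#'
#' @param hits Hit tibble.
#' @param promoters Optional promoter tibble so hitless promoters appear
#'   with a 0 count.
#' @param by Aggregation unit for `region_counts`.
#' @return Tibbles sorted deterministically (gene, then tf).
#' @export
hit_totals <- function(hits, promoters = NULL) {
  tot <- as_tibble(hits) |>
    dplyr::count(.data$gene_id, name = "total_hits")
  if (!is.null(promoters)) {
    tot <- tibble(gene_id = promoters$gene_id) |>
      left_join(tot, by = "gene_id") |>
      mutate(total_hits = dplyr::coalesce(.data$total_hits, 0L))
  }
  arrange(tot, .data$gene_id)
}

#' @rdname hit_totals
#' @export
region_counts <- function(hits, by = c("tf_name", "matrix_id")) {
  by <- match.arg(by)
  h <- as_tibble(hits)
  h$tf <- h[[by]]
  h |>
    group_by(.data$tf, .data$gene_id) |>
    summarise(
      upstream = sum(.data$region == "upstream"),
      downstream = sum(.data$region == "downstream"),
      total = n(),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id, .data$tf)
}

#' Scheme-style screening summary
#'
#' Bundles the per-promoter totals, the per-master upstream/downstream
#' counts, the per-hormone master lists and the biosynthesis/signaling
#' overlap into one object.
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @param calls `master_screen` tibble from [screen_masters()].
#' @param promoters Optional promoter tibble (zero-hit promoters included).
#' @return A list of class `screen_summary`.
#' @export
screen_summary <- function(hits, calls, promoters = NULL) {
  by <- attr(calls, "by") %||% "tf_name"
  masters <- unique(calls$tf)
  rc <- region_counts(hits, by = by)
  structure(
    list(
      promoter_totals = hit_totals(hits, promoters),
      master_region_counts = rc[rc$tf %in% masters, ],
      masters = as_tibble(calls),
      biosynthesis = masters_by_hormone(calls, "biosynthesis"),
      signaling = masters_by_hormone(calls, "signaling"),
      overlap = overlap_masters(calls)
    ),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  bio <- x$biosynthesis
  cat("Master regulatory TF screen\n")
  cat("  biosynthesis masters (union): ", length(bio$union), "\n", sep = "")
  for (h in names(bio$per_hormone)) {
    cat("    ", h, ": ", length(bio$per_hormone[[h]]), "\n", sep = "")
  }
  cat("  also mastering signaling: ", length(x$overlap),
      " (", paste(x$overlap, collapse = ", "), ")\n", sep = "")
  if (nrow(x$promoter_totals) > 0L) {
    rng <- range(x$promoter_totals$total_hits)
    cat("  per-promoter hit totals: ", rng[[1L]], "..", rng[[2L]], "\n", sep = "")
  }
  invisible(x)
}
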