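#' Scan promoter windows for motif hits below a p-value stringency
#'
#' Scores every offset of every promoter window with every PWM and reports
#' all sites whose exact tail probability is below `p_threshold` (the conventional
#' stringency for this screen is p < 1e-4). Coordinates are TSS-relative with no position 0;
#' a hit is classed `upstream` when it starts at a negative coordinate and
#' `downstream` when it starts at or after +1. Overlapping hits are all
#' reported; offsets whose L-mer contains `N` are skipped and counted.
#'
#' @param promoters Promoter tibble ([extract_promoters()] /
#'   [read_promoter_fasta()] / [simulate_promoters()]).
#' @param pfms PFM tibble from [read_jaspar_pfm()], or a list of `pwm`
#'   objects.
#' @param p_threshold Stringency; hits require `p_value < p_threshold`
#'   (default 1e-4).
#' @param both_strands Also scan the reverse complement of each window and
#'   map hits back to window coordinates (default `FALSE`: sense strand only).
#' @param background Background model; `NULL` (default) estimates it from the
#'   promoter set via [promoter_background()].
#' @param pseudocount Total per-column pseudocount for PWM construction.
#' @param scale Discretization units per bit for exact p-values.
#' @return A tibble of class `tf_scan` with columns `matrix_id`, `tf_name`,
#'   `gene_id`, `relative_start`, `relative_end`, `strand`, `score_bits`,
#'   `p_value`, `region`, sorted by gene, start, matrix. The scan
#'   configuration and per-window skipped-offset counts are attached as
#'   attributes (see [glance.tf_scan()]).
#' @export
scan_promoters <- function(promoters, pfms, p_threshold = 1e-4,
                           both_strands = FALSE, background = NULL,
                           pseudocount = 1, scale = 1000L) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0,1)")
  if (is.null(background)) background <- promoter_background(promoters)
  pwms <- as_pwm_list(pfms, background, pseudocount)
  dists <- map(pwms, score_distribution, scale = scale)
  res <- scan_core(promoters, pwms, dists, p_threshold, both_strands)
  hits <- res$hits
  skipped <- res$skipped
  structure(
    hits,
    class = c("tf_scan", class(tibble())),
    scan_config = list(
      p_threshold = p_threshold, both_strands = both_strands,
      background = background, pseudocount = pseudocount, scale = as.integer(scale),
      n_promoters = nrow(promoters), n_matrices = length(pwms),
      skipped_offsets = skipped
    )
  )
}

# hit collection given prebuilt PWMs and score distributions
scan_core <- function(promoters, pwms, dists, p_threshold, both_strands) {
  skipped <- 0L
  hit_rows <- list()
  for (k in seq_along(pwms)) {
    pw <- pwms[[k]]
    dd <- dists[[k]]
    thr_units <- threshold_units(dd, p_threshold)
    for (g in seq_len(nrow(promoters))) {
      win <- promoters$seq[[g]]
      u <- promoters$upstream_len[[g]]
      res <- scan_one(win, dd, thr_units, both_strands)
      skipped <- skipped + res$skipped
      if (nrow(res$hits) == 0L) next
      h <- res$hits
      hit_rows[[length(hit_rows) + 1L]] <- tibble(
        matrix_id = pw$matrix_id, tf_name = pw$tf_name,
        gene_id = promoters$gene_id[[g]],
        relative_start = window_pos_to_relative(h$start, u),
        relative_end = window_pos_to_relative(h$start + ncol(dd$iweights) - 1L, u),
        strand = h$strand,
        score_bits = h$units / dd$scale,
        p_value = pwm_tail(dd, h$units)
      )
    }
  }
  hits <- if (length(hit_rows) > 0L) bind_rows(hit_rows) else empty_hits()
  hits$region <- classify_region(hits$relative_start)
  hits <- arrange(hits, .data$gene_id, .data$relative_start, .data$matrix_id, .data$strand)
  list(hits = hits, skipped = skipped)
}

empty_hits <- function() {
  tibble(
    matrix_id = character(), tf_name = character(), gene_id = character(),
    relative_start = integer(), relative_end = integer(), strand = character(),
    score_bits = numeric(), p_value = numeric()
  )
}

as_pwm_list <- function(pfms, background, pseudocount) {
  if (inherits(pfms, "pwm")) return(list(pfms))
  if (is.data.frame(pfms)) {
    return(map(seq_len(nrow(pfms)), function(i) {
      build_pwm(pfms$counts[[i]], background, pseudocount,
                matrix_id = pfms$matrix_id[[i]], tf_name = pfms$tf_name[[i]])
    }))
  }
  stopifnot(all(map_lgl(pfms, inherits, "pwm")))
  pfms
}

# smallest integer score whose tail probability is (strictly) below p
threshold_units <- function(dist, p) {
  idx <- which(dist$tail < p)
  if (length(idx) == 0L) return(dist$min_score + length(dist$tail))  # unattainable
  dist$min_score + idx[[1L]] - 1L
}

# integer-score scan of one window; returns 1-based window starts and units
scan_one <- function(window, dist, thr_units, both_strands) {
  L <- ncol(dist$iweights)
  W <- nchar(window)
  if (W < L) return(list(hits = tibble(start = integer(), units = integer(), strand = character()), skipped = 0L))
  fwd <- scan_strand(window, dist$iweights, L, W)
  starts <- which(!is.na(fwd) & fwd >= thr_units)
  hits <- tibble(start = starts, units = fwd[starts], strand = rep("+", length(starts)))
  skipped <- sum(is.na(fwd))
  if (both_strands) {
    rc <- reverse_complement(window)
    rev <- scan_strand(rc, dist$iweights, L, W)
    rstarts <- which(!is.na(rev) & rev >= thr_units)
    # offset j on the reverse complement covers window positions (W-j-L+2)..(W-j+1)
    hits <- bind_rows(hits, tibble(
      start = W - rstarts - L + 2L, units = rev[rstarts],
      strand = rep("-", length(rstarts))
    ))
    skipped <- skipped + sum(is.na(rev))
  }
  list(hits = hits, skipped = skipped)
}

# total integer score at every offset (NA where the L-mer contains N)
scan_strand <- function(seqchar, iweights, L, W) {
  codes <- match(strsplit(seqchar, "")[[1L]], DNA_BASES)
  n_off <- W - L + 1L
  total <- numeric(n_off)
  for (i in seq_len(L)) {
    total <- total + iweights[, i][codes[i:(i + n_off - 1L)]]
  }
  total
}

#' Classify a hit as upstream or downstream of the TSS
#'
#' Classification is by site start: a site starting at a negative relative
#' coordinate is `upstream` (sites straddling the TSS are therefore
#' upstream); a site starting at or after +1 is `downstream`.
#'
#' @param relative_start Integer TSS-relative start coordinate(s), no 0.
#' @return Character vector `"upstream"`/`"downstream"`.
#' @export
classify_region <- function(relative_start) {
  ifelse(relative_start <= -1L, "upstream", "downstream")
}

#' Write / read a hit table as TSV
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @param path TSV path.
#' @param sidecar Optionally write `<path>.json` recording the scan
#'   configuration (threshold, background, pseudocount, scale).
#' @export
write_hits <- function(hits, path, sidecar = TRUE) {
  readr::write_tsv(as_tibble(hits), path)
  cfg <- attr(hits, "scan_config")
  if (sidecar && !is.null(cfg)) {
    jsonlite::write_json(
      c(cfg[c("p_threshold", "both_strands", "pseudocount", "scale",
              "n_promoters", "n_matrices", "skipped_offsets")],
        list(background = as.list(cfg$background))),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      matrix_id = "c", tf_name = "c", gene_id = "c",
      relative_start = "i", relative_end = "i", strand = "c",
      score_bits = "d", p_value = "d", region = "c"
    )
  )
}
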