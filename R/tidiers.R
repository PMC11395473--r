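#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for scan, screen and expression results
#'
#' `tidy()` returns the underlying tibble stripped of extra classes and
#' attributes; `glance()` returns a one-row summary (counts and the
#' configuration that produced the result).
#'
#' @param x A `tf_scan`, `master_screen` or `de_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tf_scan
#' @export
tidy.tf_scan <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname tidy.tf_scan
#' @method glance tf_scan
#' @export
glance.tf_scan <- function(x, ...) {
  cfg <- attr(x, "scan_config")
  tibble(
    n_hits = nrow(x),
    n_promoters = cfg$n_promoters,
    n_matrices = cfg$n_matrices,
    p_threshold = cfg$p_threshold,
    both_strands = cfg$both_strands,
    scale = cfg$scale,
    skipped_offsets = cfg$skipped_offsets
  )
}

#' @rdname tidy.tf_scan
#' @method tidy master_screen
#' @export
tidy.master_screen <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname tidy.tf_scan
#' @method glance master_screen
#' @export
glance.master_screen <- function(x, ...) {
  tibble(
    n_masters = dplyr::n_distinct(x$tf),
    n_calls = nrow(x),
    n_overlap = length(overlap_masters(x)),
    by = attr(x, "by"),
    min_fraction = attr(x, "min_fraction")
  )
}

#' @rdname tidy.tf_scan
#' @method tidy de_test
#' @export
tidy.de_test <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname tidy.tf_scan
#' @method glance de_test
#' @export
glance.de_test <- function(x, ...) {
  cfg <- attr(x, "de_config")
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    q = cfg$q,
    n_sim = cfg$n_sim,
    n_rep = cfg$n_rep,
    k = cfg$k
  )
}

unclass_result <- function(x) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "scan_config") <- NULL
  attr(out, "de_config") <- NULL
  attr(out, "by") <- NULL
  attr(out, "min_fraction") <- NULL
  attr(out, "gene_universe") <- NULL
  out
}
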