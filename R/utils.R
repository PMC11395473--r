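#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows rename relocate n
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_chr map_dbl map_int map_lgl
#' @importFrom stats cor rnbinom rmultinom setNames
#' @importFrom utils head packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

# run `code` under a temporary seed when one is given, untouched RNG otherwise
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# map window positions (1..width) to TSS-relative coordinates with no 0:
# the first `upstream_len` bases are -upstream_len..-1, the rest +1..+downstream_len
window_pos_to_relative <- function(pos, upstream_len) {
  as.integer(ifelse(pos <= upstream_len, pos - upstream_len - 1L, pos - upstream_len))
}

relative_to_window_pos <- function(rel, upstream_len) {
  ifelse(rel < 0L, rel + upstream_len + 1L, rel + upstream_len)
}
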