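# shared helpers: toy objects built in code, plus independent oracles

toy_pfm <- function(counts, matrix_id = "TOY", tf_name = matrix_id) {
  rownames(counts) <- c("A", "C", "G", "T")
  tibble::tibble(
    matrix_id = matrix_id, tf_name = tf_name, length = ncol(counts),
    consensus = paste(c("A", "C", "G", "T")[apply(counts, 2, which.max)], collapse = ""),
    counts = list(counts)
  )
}

# consensus-only matrix for a given DNA string
consensus_pfm <- function(seqchar, depth = 100, matrix_id = "CONS") {
  bases <- strsplit(seqchar, "")[[1]]
  counts <- matrix(0, 4, length(bases))
  counts[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- depth
  toy_pfm(counts, matrix_id)
}

toy_promoter <- function(seq, gene_id = "g1", upstream = NULL, downstream = 0L) {
  n <- nchar(seq)
  if (is.null(upstream)) upstream <- n - downstream
  tibble::tibble(
    gene_id = gene_id, strand = "+",
    upstream_len = as.integer(upstream), downstream_len = as.integer(n - upstream),
    truncated = FALSE, seq = seq
  )
}

# brute-force tail oracle: enumerate all 4^L sequences on the *same* integer
# grid as the dynamic program and suffix-sum their background probabilities
brute_force_tail <- function(dist, background) {
  iw <- dist$iweights
  L <- ncol(iw)
  stopifnot(L <= 8)
  scores <- iw[, 1]
  probs <- background
  if (L > 1) {
    for (i in 2:L) {
      scores <- as.vector(outer(scores, iw[, i], "+"))
      probs <- as.vector(outer(probs, background, "*"))
    }
  }
  agg <- rowsum(probs, scores)
  s <- as.integer(rownames(agg))
  ord <- order(s)
  tibble::tibble(
    score_units = s[ord],
    tail = unname(rev(cumsum(rev(agg[ord, 1]))))
  )
}

# brute-force master screen: explicit (tf x group x gene) membership loop
brute_force_masters <- function(hits, groups, by = "tf_name", min_fraction = 1) {
  tfs <- sort(unique(hits[[by]]))
  keys <- unique(groups[, c("hormone", "category")])
  out <- list()
  for (tf in tfs) {
    tf_genes <- unique(hits$gene_id[hits[[by]] == tf])
    for (i in seq_len(nrow(keys))) {
      gg <- groups$gene_id[groups$hormone == keys$hormone[i] &
                             groups$category == keys$category[i]]
      n_hit <- sum(gg %in% tf_genes)
      if (n_hit / length(gg) >= min_fraction) {
        out[[length(out) + 1]] <- tibble::tibble(
          tf = tf, hormone = keys$hormone[i], category = keys$category[i]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(tf = character(), hormone = character(), category = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), tf, hormone, category)
}

sort_calls <- function(calls) {
  d <- tibble::as_tibble(as.data.frame(calls)[, c("tf", "hormone", "category")])
  dplyr::arrange(d, tf, hormone, category)
}

# the bundled ground-truth fixture is expensive; build it once per test run
fixture_env <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- masterscan::build_fixture()
  fixture_env$fx
}
get_fixture_hits <- function() {
  if (is.null(fixture_env$hits)) {
    fx <- get_fixture()
    fixture_env$hits <- masterscan::scan_promoters(
      fx$promoters, fx$pfms, background = fx$background
    )
  }
  fixture_env$hits
}
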