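#' Read transcription-factor matrices in JASPAR PFM text format
#'
#' Parses the plain-text JASPAR CORE format: a header line
#' `>MATRIX_ID<tab>NAME` followed by four rows `A [ n1 n2 ... ]` (any row
#' order; parentheses optional). Rows are stored A,C,G,T with equal length and
#' strictly positive column sums.
#'
#' @param path Path to a JASPAR-format text file.
#' @return A tibble with columns `matrix_id`, `tf_name`, `length`,
#'   `consensus`, and a list-column `counts` of 4 x L numeric matrices with
#'   rownames A,C,G,T.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) abort(paste0("JASPAR file not found: ", path))
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) abort(paste0("empty JASPAR file: ", path))
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) abort("no '>' record headers found")
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- map2(starts, ends, function(s, e) {
    header <- sub("^>", "", lines[[s]])
    fields <- stringr::str_split_fixed(header, "[\t ]+", 2L)
    matrix_id <- fields[[1L]]
    tf_name <- if (fields[[2L]] == "") matrix_id else fields[[2L]]
    body <- lines[seq(s + 1L, length.out = e - s)]
    base <- toupper(substr(trimws(body), 1L, 1L))
    if (!setequal(base, DNA_BASES) || length(body) != 4L) {
      abort(paste0("matrix '", matrix_id, "': expected exactly one row per base A,C,G,T"))
    }
    vals <- map(body, function(l) {
      nums <- stringr::str_extract_all(l, "[0-9]*\\.?[0-9]+")[[1L]]
      as.numeric(nums)
    })
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L) {
      abort(paste0("matrix '", matrix_id, "': ragged rows (lengths ",
                   paste(lens, collapse = ","), ")"))
    }
    counts <- do.call(rbind, vals[order(match(base, DNA_BASES))])
    rownames(counts) <- DNA_BASES
    if (any(counts < 0)) abort(paste0("matrix '", matrix_id, "': negative count"))
    if (any(colSums(counts) <= 0)) {
      abort(paste0("matrix '", matrix_id, "': zero column sum"))
    }
    tibble(
      matrix_id = matrix_id, tf_name = tf_name,
      length = ncol(counts),
      consensus = pfm_consensus(counts),
      counts = list(counts)
    )
  })
  out <- bind_rows(recs)
  if (anyDuplicated(out$matrix_id)) {
    abort(paste0("duplicate matrix_id: ", out$matrix_id[duplicated(out$matrix_id)][[1L]]))
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pfms A tibble as returned by `read_jaspar_pfm()`.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  blocks <- pmap(
    list(pfms$matrix_id, pfms$tf_name, pfms$counts),
    function(matrix_id, tf_name, counts) {
      c(
        paste0(">", matrix_id, "\t", tf_name),
        sprintf("%s [ %s ]", DNA_BASES,
                apply(counts, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " ")))
      )
    }
  )
  writeLines(unlist(blocks), path)
  invisible(path)
}

pfm_consensus <- function(counts) {
  paste(DNA_BASES[apply(counts, 2L, which.max)], collapse = "")
}
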