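#' Read genome (or promoter) sequences from FASTA
#'
#' Reads a FASTA file into a tibble of uppercase DNA sequences. Only the
#' alphabet `A/C/G/T/N` is accepted after case normalization; anything else is
#' a format error, as are duplicated sequence identifiers. Identifiers are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id` and `seq`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate sequence id in '", path, "': ", dup[[1L]]))
  }
  seqs <- toupper(as.character(set))
  bad <- stringr::str_locate(seqs, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[[1L]]
    abort(paste0(
      "illegal character '", substr(seqs[[i]], bad[[i]], bad[[i]]),
      "' at position ", bad[[i]], " of sequence '", ids[[i]], "'"
    ))
  }
  if (any(nchar(seqs) < 1L)) abort("zero-length sequence in FASTA")
  tibble(seq_id = unname(ids), seq = unname(seqs))
}

#' Read transcription start sites from BED6 or GFF3
#'
#' Normalizes both dialects to one 1-based TSS per gene: BED is 0-based
#' half-open so the `+`-strand TSS is `start + 1` and the `-`-strand TSS is
#' `end`; GFF3 is 1-based closed so the TSS is `start` (`+`) or `end` (`-`).
#' For GFF3 only `gene` features are used and `gene_id` is taken from the
#' `ID` attribute (falling back to `Name`).
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A tibble with columns `gene_id`, `seq_id`, `strand`, `tss`.
#' @export
read_tss <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("TSS file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) abort(paste0("malformed ", toupper(format), " '", path, "': ", conditionMessage(e)))
  )
  if (format == "gff3") {
    keep <- as.character(gr$type) == "gene"
    gr <- gr[keep]
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  } else {
    ids <- as.character(gr$name)
  }
  if (length(gr) == 0L) abort(paste0("no TSS records found in '", path, "'"))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort(paste0("record without strand in '", path, "' (gene ",
                 ids[which(!strand %in% c("+", "-"))[1L]] %||% "?", ")"))
  }
  if (any(is.na(ids)) || any(ids == "")) abort("TSS record without a gene id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene_id in TSS table: ", ids[duplicated(ids)][[1L]]))
  }
  # rtracklayer returns 1-based closed starts for both dialects
  tss <- ifelse(strand == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
  tibble(
    gene_id = ids,
    seq_id = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    tss = as.integer(tss)
  )
}

#' Extract TSS-anchored promoter windows
#'
#' Cuts a directional window around each TSS spanning `upstream` bases before
#' and `downstream` bases from the TSS onward (the standard screen window is
#' -5000..+1000). The TSS itself is relative position +1; there is no
#' position 0 and upstream positions are negative. Minus-strand windows are
#' reverse-complemented so the TSS always reads left to right at +1. Windows
#' running off a contig end are truncated (never padded) and flagged.
#'
#' @param genome Tibble from [read_genome_fasta()].
#' @param tss Tibble from [read_tss()].
#' @param upstream,downstream Window extent in bases (defaults 5000 and 1000).
#' @return A tibble with columns `gene_id`, `strand`, `upstream_len`,
#'   `downstream_len`, `truncated`, `seq`.
#' @export
extract_promoters <- function(genome, tss, upstream = 5000L, downstream = 1000L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  if (upstream == 0L && downstream == 0L) abort("upstream and downstream cannot both be 0")
  missing_seq <- setdiff(tss$seq_id, genome$seq_id)
  if (length(missing_seq) > 0L) {
    abort(paste0("TSS references unknown sequence: ", missing_seq[[1L]]))
  }
  seqlen <- setNames(nchar(genome$seq), genome$seq_id)
  bad <- tss$tss < 1L | tss$tss > seqlen[tss$seq_id]
  if (any(bad)) {
    abort(paste0("TSS off the sequence for gene ", tss$gene_id[bad][[1L]]))
  }
  rows <- pmap(
    list(tss$gene_id, tss$seq_id, tss$strand, tss$tss),
    function(gene_id, seq_id, strand, pos) {
      len <- seqlen[[seq_id]]
      contig <- genome$seq[genome$seq_id == seq_id]
      if (strand == "+") {
        lo <- max(1L, pos - upstream)
        hi <- min(len, pos + downstream - 1L)
        up_len <- pos - lo
        down_len <- hi - pos + 1L
        s <- substr(contig, lo, hi)
      } else {
        lo <- max(1L, pos - downstream + 1L)
        hi <- min(len, pos + upstream)
        up_len <- hi - pos
        down_len <- pos - lo + 1L
        s <- reverse_complement(substr(contig, lo, hi))
      }
      tibble(
        gene_id = gene_id, strand = strand,
        upstream_len = as.integer(up_len), downstream_len = as.integer(down_len),
        truncated = up_len < upstream || down_len < downstream,
        seq = s
      )
    }
  )
  out <- bind_rows(rows)
  if (any(out$truncated)) {
    inform(paste0(sum(out$truncated), " promoter window(s) truncated at contig ends"))
  }
  out
}

#' Write and re-read promoter windows as FASTA
#'
#' Headers carry `gene_id|strand|upstream_len|downstream_len` so TSS-relative
#' coordinates can be reconstructed without the genome.
#'
#' @param promoters Tibble from [extract_promoters()].
#' @param path Output / input FASTA path.
#' @return `write_promoter_fasta()` returns `path` invisibly;
#'   `read_promoter_fasta()` returns a promoter tibble.
#' @export
write_promoter_fasta <- function(promoters, path) {
  headers <- sprintf(
    ">%s|%s|%d|%d",
    promoters$gene_id, promoters$strand,
    promoters$upstream_len, promoters$downstream_len
  )
  writeLines(as.vector(rbind(headers, promoters$seq)), path)
  invisible(path)
}

#' @rdname write_promoter_fasta
#' @export
read_promoter_fasta <- function(path) {
  fa <- read_genome_fasta(path)
  parts <- stringr::str_split_fixed(fa$seq_id, stringr::fixed("|"), 4L)
  if (any(parts[, 4L] == "")) {
    abort("promoter FASTA headers must be 'gene_id|strand|upstream_len|downstream_len'")
  }
  out <- tibble(
    gene_id = parts[, 1L],
    strand = parts[, 2L],
    upstream_len = as.integer(parts[, 3L]),
    downstream_len = as.integer(parts[, 4L]),
    truncated = NA,
    seq = fa$seq
  )
  if (any(nchar(out$seq) != out$upstream_len + out$downstream_len)) {
    abort("promoter length does not match upstream_len + downstream_len in header")
  }
  out
}
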