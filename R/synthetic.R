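#' Simulate a position frequency matrix
#'
#' Columns put probability `sharpness` on a (random) consensus base and split
#' the remainder evenly, scaled to integer-ish counts. Sharp long matrices
#' (the default 0.95 over 12 columns is roughly 19 bits) emulate the
#' high-information plant TF matrices the screen is designed around; lower
#' sharpness gives the mixed columns typical of JASPAR CORE.
#'
#' @param length Motif length (columns).
#' @param sharpness Consensus-base probability per column, in (0.25, 1).
#' @param n_sites Count depth per column (default 100).
#' @param matrix_id,tf_name Identifiers.
#' @param seed Optional seed.
#' @return One-row PFM tibble (same shape as [read_jaspar_pfm()]).
#' @export
simulate_pfm <- function(length = 12L, sharpness = 0.95, n_sites = 100L,
                         matrix_id = "SYN0001", tf_name = matrix_id,
                         seed = NULL) {
  stopifnot(length >= 1L, sharpness > 0.25, sharpness < 1)
  with_seed_if(seed, {
    consensus <- sample(1:4, length, replace = TRUE)
    counts <- matrix(0, 4L, length, dimnames = list(DNA_BASES, NULL))
    off <- (1 - sharpness) / 3
    for (i in seq_len(length)) {
      p <- rep(off, 4L)
      p[consensus[[i]]] <- sharpness
      counts[, i] <- round(p * n_sites)
    }
    tibble(
      matrix_id = matrix_id, tf_name = tf_name, length = length,
      consensus = pfm_consensus(counts), counts = list(counts)
    )
  })
}

#' Simulate a Dirichlet-column PFM (dense score support)
#'
#' Column probabilities are drawn from a symmetric Dirichlet, giving many
#' distinct log-odds values; useful for exercising the exact p-value
#' machinery on irregular matrices.
#'
#' @param length Motif length.
#' @param alpha Dirichlet concentration (small = sharp columns).
#' @param n_sites Count depth per column.
#' @inheritParams simulate_pfm
#' @export
simulate_pfm_dirichlet <- function(length = 8L, alpha = 0.5, n_sites = 200L,
                                   matrix_id = "SYND001", tf_name = matrix_id,
                                   seed = NULL) {
  with_seed_if(seed, {
    counts <- matrix(0, 4L, length, dimnames = list(DNA_BASES, NULL))
    for (i in seq_len(length)) {
      g <- stats::rgamma(4L, shape = alpha)
      counts[, i] <- round(g / sum(g) * n_sites) + 1
    }
    tibble(
      matrix_id = matrix_id, tf_name = tf_name, length = length,
      consensus = pfm_consensus(counts), counts = list(counts)
    )
  })
}

# sample one site from PFM column probabilities (no pseudocount)
sample_motif_instance <- function(counts) {
  probs <- sweep(counts, 2L, colSums(counts), "/")
  paste(vapply(seq_len(ncol(counts)),
               function(i) sample(DNA_BASES, 1L, prob = probs[, i]),
               character(1)),
        collapse = "")
}

random_dna <- function(n, background) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = background), collapse = "")
}

#' Simulate promoter windows with planted motif instances
#'
#' Backgrounds are drawn i.i.d. from the given base composition; motif
#' instances are sampled column-wise from PFM probabilities (so recovery
#' tests see sub-consensus sites) and written at uniformly chosen
#' non-overlapping offsets. The returned ground truth records every planted
#' site. With `clean_background = TRUE` the generator additionally scans the
#' finished windows and re-draws any background segment that happens to
#' contain a chance hit of any planned motif, so the only sites passing the
#' stringency are the planted ones — the construction used by the bundled
#' ground-truth fixture.
#'
#' @param gene_ids Character vector of promoter/gene identifiers.
#' @param pfms PFM tibble (the motif universe).
#' @param plan Tibble with columns `matrix_id`, `gene_id`, `n_sites`: how
#'   many instances of each motif to plant in each promoter (genes absent
#'   from the plan get pure background).
#' @param upstream,downstream Window extent (defaults 5000/1000, the standard
#'   screen window).
#' @param background Background model (default uniform).
#' @param clean_background Scrub chance occurrences (default `FALSE`).
#' @param p_threshold,pseudocount,scale Scan settings used only when
#'   scrubbing.
#' @param seed Optional seed; everything downstream of it is deterministic.
#' @return A list with `promoters` (tibble as from [extract_promoters()]),
#'   `sites` (ground-truth tibble: `gene_id`, `matrix_id`, `relative_start`,
#'   `instance`).
#' @export
simulate_promoters <- function(gene_ids, pfms, plan,
                               upstream = 5000L, downstream = 1000L,
                               background = background_model(),
                               clean_background = FALSE,
                               p_threshold = 1e-4, pseudocount = 1,
                               scale = 1000L, seed = NULL) {
  width <- upstream + downstream
  stopifnot(width >= 1L)
  bad_gene <- setdiff(plan$gene_id, gene_ids)
  if (length(bad_gene) > 0L) abort(paste0("plan targets unknown gene: ", bad_gene[[1L]]))
  bad_mat <- setdiff(plan$matrix_id, pfms$matrix_id)
  if (length(bad_mat) > 0L) abort(paste0("plan uses unknown matrix: ", bad_mat[[1L]]))
  lens <- setNames(pfms$length, pfms$matrix_id)
  if (any(lens[plan$matrix_id] > width)) abort("motif longer than the window")

  with_seed_if(seed, {
    proms <- vector("list", length(gene_ids))
    truth <- list()
    for (g in seq_along(gene_ids)) {
      gene <- gene_ids[[g]]
      seqchars <- strsplit(random_dna(width, background), "")[[1L]]
      gplan <- plan[plan$gene_id == gene, ]
      occupied <- rep(FALSE, width)
      if (nrow(gplan) > 0L) {
        order_rows <- order(-lens[gplan$matrix_id])  # place long motifs first
        for (r in order_rows) {
          mid <- gplan$matrix_id[[r]]
          L <- lens[[mid]]
          counts <- pfms$counts[[match(mid, pfms$matrix_id)]]
          for (s in seq_len(gplan$n_sites[[r]])) {
            occ_cum <- c(0, cumsum(occupied))
            n_off <- width - L + 1L
            legal <- which(occ_cum[seq_len(n_off) + L] - occ_cum[seq_len(n_off)] == 0)
            if (length(legal) == 0L) {
              abort(paste0("overcrowded plan: no room for ", mid, " in ", gene))
            }
            o <- legal[[sample.int(length(legal), 1L)]]
            inst <- sample_motif_instance(counts)
            seqchars[o:(o + L - 1L)] <- strsplit(inst, "")[[1L]]
            occupied[o:(o + L - 1L)] <- TRUE
            truth[[length(truth) + 1L]] <- tibble(
              gene_id = gene, matrix_id = mid,
              relative_start = window_pos_to_relative(o, upstream),
              instance = inst
            )
          }
        }
      }
      proms[[g]] <- tibble(
        gene_id = gene, strand = "+",
        upstream_len = as.integer(upstream), downstream_len = as.integer(downstream),
        truncated = FALSE, seq = paste(seqchars, collapse = "")
      )
    }
    promoters <- bind_rows(proms)
    sites <- if (length(truth) > 0L) {
      bind_rows(truth) |> arrange(.data$gene_id, .data$relative_start)
    } else {
      tibble(gene_id = character(), matrix_id = character(),
             relative_start = integer(), instance = character())
    }
    if (clean_background) {
      scrubbed <- scrub_chance_sites(
        promoters, pfms, sites, background,
        p_threshold = p_threshold, pseudocount = pseudocount, scale = scale
      )
      promoters <- scrubbed$promoters
      sites <- scrubbed$sites
    }
    list(promoters = promoters, sites = sites)
  })
}

# re-draw background segments containing chance (non-planted) hits until the
# scan reports planted sites only; deterministic under the caller's seed
scrub_chance_sites <- function(promoters, pfms, sites, background,
                               p_threshold, pseudocount, scale,
                               max_rounds = 50L) {
  lens <- setNames(pfms$length, pfms$matrix_id)
  pwms <- as_pwm_list(pfms, background, pseudocount)
  dists <- map(pwms, score_distribution, scale = scale)
  planted_occ <- function(gene, upstream_len) {
    occ <- rep(FALSE, nchar(promoters$seq[promoters$gene_id == gene]))
    gs <- sites[sites$gene_id == gene, ]
    for (r in seq_len(nrow(gs))) {
      o <- relative_to_window_pos(gs$relative_start[[r]], upstream_len)
      L <- lens[[gs$matrix_id[[r]]]]
      occ[o:(o + L - 1L)] <- TRUE
    }
    occ
  }
  chance_hits <- function(prom_rows) {
    hits <- scan_core(prom_rows, pwms, dists, p_threshold, FALSE)$hits
    anti_join(hits, sites, by = c("gene_id", "matrix_id", "relative_start"))
  }
  pfm_of <- function(mid) pfms$counts[[match(mid, pfms$matrix_id)]]
  todo <- unique(chance_hits(promoters)$gene_id)
  for (gene in todo) {
    i <- match(gene, promoters$gene_id)
    u <- promoters$upstream_len[[i]]
    occ <- planted_occ(gene, u)
    for (round in seq_len(max_rounds)) {
      ch <- chance_hits(promoters[i, ])
      if (nrow(ch) == 0L) break
      if (round == max_rounds) {
        abort("could not scrub chance motif occurrences; plan too dense for the window")
      }
      seqchars <- strsplit(promoters$seq[[i]], "")[[1L]]
      for (r in seq_len(nrow(ch))) {
        o <- relative_to_window_pos(ch$relative_start[[r]], u)
        L <- lens[[ch$matrix_id[[r]]]]
        span <- o:(o + L - 1L)
        redraw <- span[!occ[span]]
        if (length(redraw) > 0L) {
          seqchars[redraw] <- sample(DNA_BASES, length(redraw),
                                     replace = TRUE, prob = background)
        }
        if (length(redraw) == 0L || round > 10L) {
          # the offending bases are (mostly) planted: re-sample the planted
          # instances the hit overlaps, keeping the ground truth in step
          gs <- which(sites$gene_id == gene)
          for (k in gs) {
            ps <- relative_to_window_pos(sites$relative_start[[k]], u)
            pl <- lens[[sites$matrix_id[[k]]]]
            if (ps <= span[[length(span)]] && ps + pl - 1L >= span[[1L]]) {
              inst <- sample_motif_instance(pfm_of(sites$matrix_id[[k]]))
              seqchars[ps:(ps + pl - 1L)] <- strsplit(inst, "")[[1L]]
              sites$instance[[k]] <- inst
            }
          }
        }
      }
      promoters$seq[[i]] <- paste(seqchars, collapse = "")
    }
  }
  list(promoters = promoters, sites = sites)
}

#' Simulate a set of mutually dissimilar sharp PFMs
#'
#' Draws consensus sequences by rejection so that no two motifs (and no
#' motif against a shifted copy of itself) share more than `max_shared`
#' aligned consensus bases at any relative shift. Distinguishable motifs
#' keep one factor's planted sites from doubling as near-threshold sites of
#' another — the property a ground-truth benchmark needs.
#'
#' @param n Number of matrices.
#' @param length,sharpness,n_sites As in [simulate_pfm()].
#' @param matrix_ids,tf_names Identifiers (defaults generated).
#' @param max_shared Maximum aligned consensus matches allowed between any
#'   two (shifted) motifs (default `length %/% 2`).
#' @param seed Optional seed.
#' @return PFM tibble with `n` rows.
#' @export
simulate_pfm_set <- function(n, length = 15L, sharpness = 0.95, n_sites = 100L,
                             matrix_ids = sprintf("SM%04d", seq_len(n)),
                             tf_names = matrix_ids,
                             max_shared = length %/% 2L, seed = NULL) {
  max_matches <- function(a, b) {
    # best aligned-match count of consensus integer vectors over all shifts
    L <- base::length(a)
    best <- 0L
    for (sh in seq(-(L - 1L), L - 1L)) {
      ia <- max(1L, 1L + sh):min(L, L + sh)
      ib <- ia - sh
      best <- max(best, sum(a[ia] == b[ib]))
    }
    best
  }
  self_ok <- function(a) {
    L <- base::length(a)
    all(vapply(seq_len(L - 1L),
               function(sh) sum(a[(1L + sh):L] == a[1L:(L - sh)]),
               integer(1)) <= max_shared)
  }
  with_seed_if(seed, {
    consensi <- list()
    while (base::length(consensi) < n) {
      cand <- sample.int(4L, length, replace = TRUE)
      if (!self_ok(cand)) next
      if (any(map_lgl(consensi, function(c0) max_matches(cand, c0) > max_shared))) next
      consensi[[base::length(consensi) + 1L]] <- cand
    }
    off <- (1 - sharpness) / 3
    bind_rows(lapply(seq_len(n), function(k) {
      counts <- matrix(round(off * n_sites), 4L, length,
                       dimnames = list(DNA_BASES, NULL))
      counts[cbind(consensi[[k]], seq_len(length))] <- round(sharpness * n_sites)
      tibble(
        matrix_id = matrix_ids[[k]], tf_name = tf_names[[k]],
        length = length, consensus = pfm_consensus(counts),
        counts = list(counts)
      )
    }))
  })
}

#' Simulate a control/treated count table with planted fold changes
#'
#' Control counts are negative binomial around gene means; treated counts use
#' `mean * fold`. Mean vectors are rescaled per sample so their sums equal
#' the target library sizes, hence a planted fold is (up to the small
#' renormalization over all genes) a planted CPM ratio.
#'
#' @param gene_ids Gene identifiers.
#' @param means Per-gene expected counts in the control library (recycled).
#' @param folds Per-gene fold change (recycled; 1 = null).
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2); 0 gives
#'   Poisson.
#' @param lib_control,lib_treated Target library sizes.
#' @param seed Optional seed.
#' @return A list with `counts` (tibble `gene_id`, `control`, `treated`) and
#'   `de_truth` (tibble `gene_id`, `mean`, `fold`).
#' @export
simulate_counts <- function(gene_ids, means, folds = 1, dispersion = 0.05,
                            lib_control = 2e6, lib_treated = 2e6, seed = NULL) {
  n <- length(gene_ids)
  means <- rep_len(means, n)
  folds <- rep_len(folds, n)
  if (any(means <= 0) || any(folds <= 0)) abort("means and folds must be > 0")
  if (lib_control <= 0 || lib_treated <= 0) abort("library sizes must be > 0")
  if (dispersion < 0) abort("dispersion must be >= 0")
  with_seed_if(seed, {
    mu_c <- means / sum(means) * lib_control
    mu_t <- (means * folds) / sum(means * folds) * lib_treated
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
    }
    counts <- tibble(
      gene_id = gene_ids,
      control = as.numeric(draw(mu_c)),
      treated = as.numeric(draw(mu_t))
    )
    list(counts = counts, de_truth = tibble(gene_id = gene_ids, mean = means, fold = folds))
  })
}

#' Configuration of the bundled ground-truth fixture
#'
#' A fully synthetic study with the cardinalities typical of a phytohormone
#' master-regulator screen: 32 biosynthesis genes (8 per hormone) and 9
#' signaling genes (SA 3, JA/ABA/ET 2 each); 18 TF matrices of which 14 are
#' planted masters — per-hormone biosynthesis masters 4 SA / 9 JA / 5 ABA /
#' 10 ET with a union of 14, 7 of which also master a signaling group — plus
#' 4 decoy TFs planted in proper subsets of groups. Master TF genes carry
#' planted expression fold changes (the lead DOF-like factor gets a 3.25x
#' CPM ratio, i.e. a +225% change). All names are synthetic; nothing here is
#' real data.
#'
#' @param seed Integer seed controlling every random draw (default 20240823).
#' @param upstream,downstream Window extent (defaults 5000/1000).
#' @param sites_per_gene Planted instances per (master TF, target gene)
#'   (default 3; promoters in this screen typically carry several sites per
#'   factor).
#' @return A config list consumed by [build_fixture()] / [write_fixture()].
#' @export
fixture_config <- function(seed = 20240823L, upstream = 5000L,
                                downstream = 1000L, sites_per_gene = 3L) {
  hormones <- c("SA", "JA", "ABA", "ET")
  bio_genes <- lapply(hormones, function(h) sprintf("%s_BIO%02d", h, 1:8))
  names(bio_genes) <- hormones
  sig_n <- c(SA = 3L, JA = 2L, ABA = 2L, ET = 2L)
  sig_genes <- lapply(hormones, function(h) sprintf("%s_SIG%02d", h, seq_len(sig_n[[h]])))
  names(sig_genes) <- hormones

  masters <- c(sprintf("synDOF%d", 1:9), "synAHL1", "synMADS1", "synJMJ1",
               "synERF1", "synERF2")
  decoys <- c("synWRKY1", "synMYB1", "synBZIP1", "synNAC1")
  # biosynthesis group membership: SA = T1..T4, JA = T1..T9, ABA = T10..T14,
  # ET = T5..T14 -> per-hormone counts 4/9/5/10, union 14
  bio_membership <- list(
    SA = masters[1:4], JA = masters[1:9], ABA = masters[10:14], ET = masters[5:14]
  )
  # 7 masters also master one signaling group each
  sig_membership <- list(
    SA = masters[c(1L, 2L)], JA = masters[c(5L, 6L)],
    ABA = masters[c(10L, 11L)], ET = masters[14L]
  )
  list(
    seed = as.integer(seed),
    upstream = as.integer(upstream), downstream = as.integer(downstream),
    sites_per_gene = as.integer(sites_per_gene),
    background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    motif_length = 15L, motif_sharpness = 0.95,
    hormones = hormones, bio_genes = bio_genes, sig_genes = sig_genes,
    masters = masters, decoys = decoys,
    bio_membership = bio_membership, sig_membership = sig_membership,
    p_threshold = 1e-4, pseudocount = 1, scale = 1000L,
    lead_fold = 3.25, lib_control = 2e6, lib_treated = 2e6,
    n_background_genes = 200L, dispersion = 0.05
  )
}

#' Build the bundled ground-truth fixture in memory
#'
#' @param cfg Config list from [fixture_config()].
#' @return A list with `promoters`, `pfms`, `groups`, `counts`, `truth`
#'   (planted sites, true masters per group, overlap, DE folds) and the
#'   background model.
#' @export
build_fixture <- function(cfg = fixture_config()) {
  withr::with_seed(cfg$seed, {
    tfs <- c(cfg$masters, cfg$decoys)
    pfms <- simulate_pfm_set(length(tfs), cfg$motif_length, cfg$motif_sharpness,
                             tf_names = tfs)
    groups <- bind_rows(
      bind_rows(lapply(cfg$hormones, function(h) {
        tibble(hormone = h, category = "biosynthesis", gene_id = cfg$bio_genes[[h]])
      })),
      bind_rows(lapply(cfg$hormones, function(h) {
        tibble(hormone = h, category = "signaling", gene_id = cfg$sig_genes[[h]])
      }))
    )
    id_of <- setNames(pfms$matrix_id, pfms$tf_name)
    plan_rows <- list()
    add_plan <- function(tf, genes) {
      plan_rows[[length(plan_rows) + 1L]] <<- tibble(
        matrix_id = id_of[[tf]], gene_id = genes, n_sites = cfg$sites_per_gene
      )
    }
    for (h in cfg$hormones) {
      for (tf in cfg$bio_membership[[h]]) add_plan(tf, cfg$bio_genes[[h]])
      for (tf in cfg$sig_membership[[h]]) add_plan(tf, cfg$sig_genes[[h]])
    }
    # decoys: sites in all but one gene of one biosynthesis group each, so
    # they show up in the hit table but never pass the intersection rule
    for (i in seq_along(cfg$decoys)) {
      h <- cfg$hormones[[(i - 1L) %% length(cfg$hormones) + 1L]]
      add_plan(cfg$decoys[[i]], cfg$bio_genes[[h]][-1L])
    }
    plan <- bind_rows(plan_rows)
    gene_ids <- groups$gene_id
    bg <- background_model(cfg$background)
    sim <- simulate_promoters(
      gene_ids, pfms, plan,
      upstream = cfg$upstream, downstream = cfg$downstream,
      background = bg, clean_background = TRUE,
      p_threshold = cfg$p_threshold, pseudocount = cfg$pseudocount,
      scale = cfg$scale
    )
    true_masters <- bind_rows(
      bind_rows(lapply(cfg$hormones, function(h) {
        tibble(tf = cfg$bio_membership[[h]], hormone = h, category = "biosynthesis")
      })),
      bind_rows(lapply(cfg$hormones, function(h) {
        tibble(tf = cfg$sig_membership[[h]], hormone = h, category = "signaling")
      }))
    ) |> arrange(.data$tf, .data$hormone, .data$category)

    # count table: pathway genes + TF genes + background filler
    expr_genes <- c(gene_ids, tfs, sprintf("BG%04d", seq_len(cfg$n_background_genes)))
    means <- stats::rlnorm(length(expr_genes), meanlog = log(500), sdlog = 1)
    folds <- rep(1, length(expr_genes))
    names(folds) <- expr_genes
    names(means) <- expr_genes
    means[tfs[1L]] <- 2000  # lead factor well-expressed so the 225% is clean
    folds[tfs[1L]] <- cfg$lead_fold
    other_master_folds <- c(3.0, 2.74, 2.02, 1.71)  # 200%/174%/102%/71%-style changes
    folds[cfg$masters[c(10L, 2L, 13L, 14L)]] <- other_master_folds
    cnt <- simulate_counts(
      expr_genes, means = means, folds = unname(folds),
      dispersion = cfg$dispersion,
      lib_control = cfg$lib_control, lib_treated = cfg$lib_treated
    )
    list(
      promoters = sim$promoters, pfms = pfms, groups = groups,
      counts = cnt$counts, background = bg,
      truth = list(
        sites = sim$sites,
        masters = true_masters,
        overlap = sort(unique(intersect(
          true_masters$tf[true_masters$category == "biosynthesis"],
          true_masters$tf[true_masters$category == "signaling"]
        ))),
        de = cnt$de_truth
      ),
      config = cfg
    )
  })
}

#' Write a fixture directory
#'
#' Emits `promoters.fasta`, `tss.bed`, `motifs.jaspar`, `counts.tsv`,
#' `groups.yaml`, `ground_truth.json` and `config.yaml`. The promoter FASTA
#' doubles as the genome: `tss.bed` places each gene's TSS inside its own
#' promoter contig, so the coordinate-extraction stage can be exercised on
#' the fixture. Byte-identical across runs at a fixed seed.
#'
#' @param fixture List from [build_fixture()] (or a config list, which is
#'   built first).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture = fixture_config(), dir) {
  if (!is.null(fixture$seed)) fixture <- build_fixture(fixture)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  prom <- fixture$promoters
  write_promoter_fasta(prom, p("promoters.fasta"))
  # BED6 within the promoter contigs: TSS base is position upstream_len + 1
  bed <- tibble(
    chrom = prom$gene_id,
    start = prom$upstream_len,  # 0-based start of the TSS base
    end = prom$upstream_len + 1L,
    name = prom$gene_id, score = 0L, strand = "+"
  )
  readr::write_tsv(bed, p("tss.bed"), col_names = FALSE)
  write_jaspar_pfm(fixture$pfms, p("motifs.jaspar"))
  readr::write_tsv(fixture$counts, p("counts.tsv"))
  write_groups(fixture$groups, p("groups.yaml"))
  jsonlite::write_json(
    list(
      sites = fixture$truth$sites,
      masters = fixture$truth$masters,
      overlap = fixture$truth$overlap,
      de = fixture$truth$de,
      background = as.list(fixture$background)
    ),
    p("ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  yaml::write_yaml(fixture$config, p("config.yaml"))
  invisible(dir)
}
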