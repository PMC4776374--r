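# Synthetic-data module: generates every input the pipeline consumes with
# planted ground truth. Each generator is a pure function of (config, seed):
# private RNG streams (fixed offsets from config$seed) make outputs
# reproducible and independent of call order.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) sample(AA20, n, replace = TRUE)

mutate_aa <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  chars
}

# one realized 24-residue LRR repeat: conserved consensus positions kept with
# high probability, degenerate positions random
realize_lrr <- function(fidelity = 0.9) {
  cons <- strsplit(lrr_consensus(), "")[[1]]
  out <- character(length(cons))
  for (i in seq_along(cons)) {
    if (cons[i] == "X" || stats::runif(1) > fidelity) out[i] <- sample(AA20, 1)
    else out[i] <- cons[i]
  }
  out
}

KINASE_LEN <- 280L

#' Generate a synthetic proteome with planted domain architecture
#'
#' Creates `n_family` true family proteins (each with at least one LRR and
#' one kinase domain annotation, lengths drawn within 423-1563 residues),
#' `n_decoy` decoys cycling over the classes `lrr_only`, `kinase_only` and
#' `neither`, and a reference protein set carrying group labels. Kinase
#' domains within a group descend from one group ancestor (within-group
#' divergence about 3%, between-group essentially random), which is what the
#' phylogeny module later exploits for group assignment.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_proteome` with elements `proteins`
#'   (`AAStringSet`, family then decoys), `reference` (`AAStringSet`),
#'   `annotations` (data frame: gene_id, domain_type, start, end, score),
#'   `ref_groups` (data frame: gene_id, group) and `truth` (per-gene labels).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed + 11L, {
    n_fam <- config$n_family
    n_dec <- config$n_decoy
    groups <- paste0("G", seq_len(config$n_groups))
    ancestors <- lapply(groups, function(g) random_aa(KINASE_LEN))
    names(ancestors) <- groups

    ann <- list()
    truth <- list()
    seqs <- character(0)

    build_protein <- function(id, len, group, want_lrr, want_kinase,
                              kinase_rate, is_family, decoy_class) {
      chars <- random_aa(len)
      has_sp <- is_family && stats::runif(1) < 0.8
      rows <- list()
      if (has_sp) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = id, domain_type = "signal_peptide",
          start = 1L, end = 25L, score = round(stats::runif(1, 0.6, 1), 3))
      }
      n_lrr <- 0L
      if (want_lrr) {
        lo <- if (has_sp) 30L else 5L
        hi <- if (want_kinase) len - KINASE_LEN - 60L else len - 30L
        n_fit <- max(1L, (hi - lo) %/% 34L)
        n_lrr <- min(sample(3:12, 1), n_fit)
        pos <- lo
        for (r in seq_len(n_lrr)) {
          rep_seq <- realize_lrr()
          chars[pos:(pos + 23L)] <- rep_seq
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = id, domain_type = "LRR",
            start = pos, end = pos + 23L,
            score = round(stats::runif(1, 15, 40), 2))
          pos <- pos + 24L + sample(0:10, 1)
        }
      }
      n_tm <- 0L
      k_start <- NA_integer_
      if (want_kinase) {
        k_start <- len - KINASE_LEN - 7L
        kin <- mutate_aa(ancestors[[group]], kinase_rate)
        chars[k_start:(k_start + KINASE_LEN - 1L)] <- kin
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = id, domain_type = "kinase",
          start = k_start, end = k_start + KINASE_LEN - 1L,
          score = round(stats::runif(1, 100, 300), 2))
        if (stats::runif(1) < 0.95) {
          n_tm <- 1L
          tm_start <- k_start - 30L
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = id, domain_type = "TM",
            start = tm_start, end = tm_start + 20L,
            score = round(stats::runif(1, 0.7, 1), 3))
        }
      }
      list(seq = paste(chars, collapse = ""),
           rows = rows,
           truth = data.frame(
             gene_id = id, is_family = is_family,
             decoy_class = decoy_class %||% NA_character_,
             group = group %||% NA_character_,
             length = len,
             kinase_start = k_start,
             kinase_end = if (is.na(k_start)) NA_integer_
                          else k_start + KINASE_LEN - 1L,
             n_lrr = n_lrr, n_tm = n_tm,
             has_signal_peptide = has_sp,
             stringsAsFactors = FALSE))
    }

    add <- function(p) {
      seqs[p$truth$gene_id] <<- p$seq
      ann[[length(ann) + 1]] <<- do.call(rbind, p$rows)
      truth[[length(truth) + 1]] <<- p$truth
    }

    if (n_fam > 0) {
      fam_ids <- sprintf("GmSYN%04d", seq_len(n_fam))
      fam_groups <- groups[(seq_len(n_fam) - 1L) %% length(groups) + 1L]
      for (i in seq_len(n_fam)) {
        len <- sample(423:1563, 1)
        add(build_protein(fam_ids[i], len, fam_groups[i],
                          want_lrr = TRUE, want_kinase = TRUE,
                          kinase_rate = 0.03, is_family = TRUE,
                          decoy_class = NULL))
      }
    }
    if (n_dec > 0) {
      classes <- rep(c("lrr_only", "kinase_only", "neither"),
                     length.out = n_dec)
      for (i in seq_len(n_dec)) {
        id <- sprintf("DECOY%04d", i)
        len <- sample(350:1200, 1)
        cl <- classes[i]
        add(build_protein(id, len,
                          group = if (cl == "kinase_only")
                            sample(groups, 1) else NULL,
                          want_lrr = cl == "lrr_only",
                          want_kinase = cl == "kinase_only",
                          kinase_rate = 0.15, is_family = FALSE,
                          decoy_class = cl))
      }
    }

    ref <- character(0)
    ref_rows <- list()
    ref_truth <- list()
    if (config$n_refs_per_group > 0 && n_fam > 0) {
      for (g in groups) {
        for (i in seq_len(config$n_refs_per_group)) {
          id <- sprintf("AtSYN_%s_%d", g, i)
          len <- 620L
          chars <- random_aa(len)
          k_start <- len - KINASE_LEN - 7L
          chars[k_start:(k_start + KINASE_LEN - 1L)] <-
            mutate_aa(ancestors[[g]], 0.08)
          pos <- 30L
          for (r in 1:3) {
            chars[pos:(pos + 23L)] <- realize_lrr()
            pos <- pos + 30L
          }
          ref[id] <- paste(chars, collapse = "")
          ref_rows[[length(ref_rows) + 1]] <- data.frame(
            gene_id = id, group = g, stringsAsFactors = FALSE)
          ref_truth[[length(ref_truth) + 1]] <- data.frame(
            gene_id = id, kinase_start = k_start,
            kinase_end = k_start + KINASE_LEN - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }

    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(gene_id = character(), domain_type = character(),
                 start = integer(), end = integer(), score = numeric())
    rownames(annotations) <- NULL
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), is_family = logical())
    rownames(truth_df) <- NULL

    structure(list(
      proteins = Biostrings::AAStringSet(seqs),
      reference = Biostrings::AAStringSet(ref),
      annotations = annotations,
      ref_groups = if (length(ref_rows)) do.call(rbind, ref_rows) else
        data.frame(gene_id = character(), group = character()),
      ref_kinase = if (length(ref_truth)) do.call(rbind, ref_truth) else
        data.frame(gene_id = character()),
      truth = truth_df
    ), class = "sim_proteome")
  })
}

# paper-shaped intron-count sampler (about half the family has one intron,
# a tail reaches past ten)
sample_intron_count <- function(n) {
  k <- c(0, 1, 2, 3, 4, 5, 7, 12)
  w <- c(26, 217, 46, 19, 4, 4, 55, 96)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

aa_codon_table <- function() {
  if (is.null(.fe$aa_codons)) {
    code <- genetic_code()
    .fe$aa_codons <- split(names(code), unname(code))
  }
  .fe$aa_codons
}

# back-translate a protein to a CDS (uniform synonymous codon choice) and
# append a stop codon
backtranslate_protein <- function(protein) {
  tab <- aa_codon_table()
  aa <- strsplit(protein, "")[[1]]
  cods <- vapply(aa, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(c(cods, sample(tab[["*"]], 1)), collapse = "")
}

#' Generate gene coordinates with planted tandem clusters
#'
#' Places the simulated genes on chromosomes: genes named in the tandem
#' cluster layout are laid out consecutively at the stated start-to-start
#' spacing; all other genes are spaced strictly more than the tandem window
#' apart, so the planted cluster memberships are exactly recoverable by the
#' 200-kb chaining rule. Also builds each gene's exon/CDS structure and a
#' CDS sequence back-translated from its protein.
#'
#' @param config a [sim_config()].
#' @param proteome optional result of [generate_proteome()] for the same
#'   config (regenerated if missing).
#' @return list of class `gene_models`: `genes` (gene_id, chromosome, start,
#'   end, strand, n_exons), `exons`, `cds_spans` (per-gene genomic
#'   intervals), `cds_seq` (named character), `truth_clusters` (cluster_id,
#'   gene_id) and `window`.
#' @export
generate_gene_coordinates <- function(config, proteome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(proteome)) proteome <- generate_proteome(config)
  with_rng(config$seed + 23L, {
    tr <- proteome$truth
    if (nrow(tr) == 0) {
      return(structure(list(
        genes = data.frame(), exons = data.frame(), cds_spans = data.frame(),
        cds_seq = character(), truth_clusters = data.frame(),
        window = config$tandem_window), class = "gene_models"))
    }
    ids <- tr$gene_id
    fam_ids <- tr$gene_id[tr$is_family]
    cs <- config$tandem_cluster_spec
    n_clustered <- if (nrow(cs)) sum(cs$n) else 0L
    if (n_clustered > length(fam_ids))
      stop("more clustered genes requested than family genes available")
    cluster_ids <- if (n_clustered)
      utils::tail(fam_ids, n_clustered) else character(0)
    rest <- setdiff(ids, cluster_ids)
    unplaced <- character(0)
    if (config$n_unplaced > 0) {
      fam_rest <- intersect(rest, fam_ids)
      unplaced <- utils::tail(fam_rest, min(config$n_unplaced,
                                            length(fam_rest)))
      rest <- setdiff(rest, unplaced)
    }

    aa_len <- stats::setNames(tr$length, tr$gene_id)
    intron_n <- stats::setNames(sample_intron_count(length(ids)), ids)
    intron_n[cluster_ids] <- sample(0:2, length(cluster_ids), replace = TRUE)

    gene_len <- function(id) {
      cds <- 3L * (aa_len[[id]] + 1L)
      ni <- intron_n[[id]]
      if (ni == 0) return(cds)
      cds + sum(sample(100:2000, ni, replace = TRUE))
    }

    genes <- list(); exons <- list(); cds_spans <- list()
    cds_seq <- character(0)
    place_gene <- function(id, chrom, start) {
      ni <- intron_n[[id]]
      cds_len <- 3L * (aa_len[[id]] + 1L)
      introns <- if (ni > 0) sample(100:2000, ni, replace = TRUE) else integer(0)
      cuts <- if (ni > 0) sort(sample(seq_len(cds_len - 1L), ni)) else integer(0)
      piece <- diff(c(0L, cuts, cds_len))
      ex_start <- integer(ni + 1L); ex_end <- integer(ni + 1L)
      cur <- start
      for (e in seq_len(ni + 1L)) {
        ex_start[e] <- cur
        ex_end[e] <- cur + piece[e] - 1L
        cur <- ex_end[e] + 1L + if (e <= ni) introns[e] else 0L
      }
      end <- ex_end[ni + 1L]
      strand <- sample(c("+", "-"), 1)
      genes[[length(genes) + 1]] <<- data.frame(
        gene_id = id, chromosome = chrom, start = start, end = end,
        strand = strand, n_exons = ni + 1L, stringsAsFactors = FALSE)
      exons[[length(exons) + 1]] <<- data.frame(
        gene_id = id, exon = seq_len(ni + 1L),
        start = ex_start, end = ex_end, stringsAsFactors = FALSE)
      cds_seq[[id]] <<- backtranslate_protein(
        as.character(proteome$proteins[[id]]))
      end
    }

    chrom_name <- function(i) sprintf("Chr%02d", i)
    # cursor per chromosome: last placed start and last placed end
    last_start <- stats::setNames(rep(-Inf, config$n_chromosomes),
                                  chrom_name(seq_len(config$n_chromosomes)))
    last_end <- stats::setNames(rep(0, config$n_chromosomes),
                                names(last_start))
    w <- config$tandem_window

    # dispersed genes, round-robin over chromosomes
    if (length(rest)) {
      chrom_of <- chrom_name((seq_along(rest) - 1L) %% config$n_chromosomes + 1L)
      for (i in seq_along(rest)) {
        id <- rest[i]; ch <- chrom_of[i]
        gap <- w + round(stats::runif(1, 5e4, 2.5e5))
        start <- max(last_start[[ch]] + gap, last_end[[ch]] + 1e4)
        start <- round(max(start, 5e4))
        if (start + gene_len(id) > config$chromosome_length)
          stop("cannot place gene ", id, " on ", ch,
               ": chromosome too short for requested layout")
        e <- place_gene(id, ch, start)
        last_start[[ch]] <- start; last_end[[ch]] <- e
      }
    }

    truth_clusters <- list()
    if (nrow(cs)) {
      take <- 0L
      for (ci in seq_len(nrow(cs))) {
        ch_i <- cs$chromosome[ci]
        if (ch_i > config$n_chromosomes)
          stop("tandem_cluster_spec names chromosome ", ch_i,
               " but only ", config$n_chromosomes, " exist")
        ch <- chrom_name(ch_i)
        members <- cluster_ids[(take + 1L):(take + cs$n[ci])]
        take <- take + cs$n[ci]
        start <- max(last_start[[ch]] + w + 3e5, last_end[[ch]] + w + 3e5, 5e4)
        start <- round(start)
        for (m in seq_along(members)) {
          id <- members[m]
          if (start + gene_len(id) > config$chromosome_length)
            stop("cannot place tandem cluster on chromosome ", ch_i,
                 ": chromosome too short for requested layout")
          e <- place_gene(id, ch, start)
          last_start[[ch]] <- start; last_end[[ch]] <- e
          if (m < length(members)) start <- start + cs$spacing[ci]
        }
        truth_clusters[[ci]] <- data.frame(
          cluster_id = sprintf("TCLUST%02d", ci), gene_id = members,
          stringsAsFactors = FALSE)
      }
    }
    for (id in unplaced) place_gene(id, "scaffold_1", 5e4)

    genes_df <- do.call(rbind, genes)
    exons_df <- do.call(rbind, exons)
    rownames(genes_df) <- rownames(exons_df) <- NULL
    structure(list(
      genes = genes_df,
      exons = exons_df,
      cds_spans = exons_df,  # all-coding gene models: CDS == exons
      cds_seq = cds_seq,
      truth_clusters = if (length(truth_clusters))
        do.call(rbind, truth_clusters) else
        data.frame(cluster_id = character(), gene_id = character()),
      window = w
    ), class = "gene_models")
  })
}

# all synonymous (or nonsynonymous) single-nucleotide variants of a codon,
# never a stop
codon_snv_options <- function(codon, synonymous) {
  code <- genetic_code()
  aa <- code[[codon]]
  cv <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), cv[pos])) {
      alt <- cv; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (code[[altc]] == "*") next
      if ((code[[altc]] == aa) == synonymous) out <- c(out, altc)
    }
  }
  out
}

#' Generate paralog CDS pairs with exact planted substitution counts
#'
#' For each requested pair an ancestral stop-free codon sequence of length
#' `L` is drawn, then a copy receives exactly `sd` synonymous and `nd`
#' nonsynonymous single-nucleotide edits, each in a distinct previously
#' unedited codon and never creating a stop. Because every edited codon
#' differs at a single site, the Nei-Gojobori pathway counts recover the
#' planted (`sd`, `nd`) exactly. Rows may instead give `target_ks` /
#' `target_ka`; these are converted to counts using the ancestral sequence's
#' synonymous/nonsynonymous site totals and the inverse Jukes-Cantor map.
#'
#' @param config a [sim_config()].
#' @param gene_ids optional ids to assign pair members to (defaults to the
#'   head of the simulated family, two per pair).
#' @return list of class `sim_pairs`: `cds` (`DNAStringSet`), `pairs`
#'   (gene_a, gene_b), `truth` (sd_true, nd_true, L per pair).
#' @export
generate_duplicate_pairs <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$duplicate_pair_spec
  if (is.null(spec) || nrow(spec) == 0) {
    return(structure(list(cds = Biostrings::DNAStringSet(),
                          pairs = data.frame(), truth = data.frame()),
                     class = "sim_pairs"))
  }
  if (is.null(gene_ids)) {
    if (config$n_family < 2 * nrow(spec))
      stop("n_family too small to host ", nrow(spec), " duplicate pairs")
    gene_ids <- sprintf("GmSYN%04d", seq_len(2 * nrow(spec)))
  }
  stopifnot(length(gene_ids) == 2 * nrow(spec))
  with_rng(config$seed + 37L, {
    seqs <- character(0)
    pairs <- list(); truth <- list()
    for (i in seq_len(nrow(spec))) {
      L <- as.integer(spec$L[i])
      if (L < 30) stop("pair ", i, ": L must be >= 30 codons")
      anc <- sample(sense_codons(), L, replace = TRUE)
      if (!is.null(spec$sd) && !is.na(spec$sd[i])) {
        sd_t <- as.integer(spec$sd[i]); nd_t <- as.integer(spec$nd[i])
      } else {
        S0 <- sum(codon_syn_sites(anc))
        N0 <- 3 * L - S0
        pS <- 0.75 * (1 - exp(-spec$target_ks[i] / 0.75))
        pN <- 0.75 * (1 - exp(-(spec$target_ka[i] %||% 0) / 0.75))
        sd_t <- as.integer(round(pS * S0))
        nd_t <- as.integer(round(pN * N0))
      }
      if (sd_t + nd_t > L)
        stop("pair ", i, ": sd + nd exceeds codon length L")
      der <- anc
      slots <- sample(L, sd_t + nd_t)
      syn_slots <- slots[seq_len(sd_t)]
      non_slots <- slots[sd_t + seq_len(nd_t)]
      edit <- function(idx, synonymous) {
        for (j in idx) {
          placed <- FALSE
          for (try in 1:100) {
            opts <- codon_snv_options(der[j], synonymous)
            if (length(opts)) {
              der[j] <<- sample(opts, 1)
              placed <- TRUE
              break
            }
            # codon admits no such change (e.g. ATG/TGG for synonymous):
            # swap target codon with an untouched one
            free <- setdiff(seq_len(L), slots)
            if (!length(free)) break
            k <- sample(free, 1)
            slots <<- c(slots, k)
            j <- k
          }
          if (!placed) stop("could not place edit without creating a stop")
        }
      }
      edit(syn_slots, TRUE)
      edit(non_slots, FALSE)
      ga <- gene_ids[2 * i - 1]; gb <- gene_ids[2 * i]
      seqs[ga] <- paste(anc, collapse = "")
      seqs[gb] <- paste(der, collapse = "")
      pairs[[i]] <- data.frame(gene_a = ga, gene_b = gb,
                               stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(gene_a = ga, gene_b = gb, sd_true = sd_t,
                               nd_true = nd_t, L = L,
                               stringsAsFactors = FALSE)
    }
    structure(list(cds = Biostrings::DNAStringSet(seqs),
                   pairs = do.call(rbind, pairs),
                   truth = do.call(rbind, truth)),
              class = "sim_pairs")
  })
}

atlas_tissues <- function(n) {
  base <- c("roots", "root_hairs", "nodules", "leaves", "stems",
            "flowers", "SAM", "pods", "seeds")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("tissue%02d", seq_len(n - length(base))))
}

#' Generate a tissue expression atlas with planted specificity
#'
#' A `specificity_fraction` of family genes receive one dominant tissue whose
#' mean is at least 8x the background mean (draws are bounded so the planted
#' tissue is always the row maximum); remaining genes are near-uniform noise.
#' Duplicate pairs are planted as `shared` (one profile, rescaled: Pearson r
#' about 1) or `contrasting` (dominant expression in different tissues) per
#' the `expr_mode` column of the pair layout.
#'
#' @param config a [sim_config()].
#' @param proteome optional [generate_proteome()] result.
#' @param pairs optional [generate_duplicate_pairs()] result.
#' @return list of class `sim_expression`: `matrix` (genes x tissues),
#'   `truth` (gene_id, specific_tissue) and `pair_truth` (gene_a, gene_b,
#'   expr_mode).
#' @export
generate_expression <- function(config, proteome = NULL, pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(proteome)) proteome <- generate_proteome(config)
  if (is.null(pairs)) pairs <- generate_duplicate_pairs(config)
  with_rng(config$seed + 51L, {
    ids <- proteome$truth$gene_id[proteome$truth$is_family]
    tissues <- atlas_tissues(config$n_tissues)
    n <- length(ids); k <- length(tissues)
    mu <- 5
    m <- matrix(mu * stats::runif(n * k, 0.8, 1.2), n, k,
                dimnames = list(ids, tissues))
    n_spec <- round(config$specificity_fraction * n)
    spec_genes <- if (n_spec > 0) sample(ids, n_spec) else character(0)
    spec_tissue <- stats::setNames(rep(NA_character_, n), ids)
    for (g in spec_genes) {
      t <- sample(tissues, 1)
      m[g, t] <- mu * stats::runif(1, 8, 12)
      spec_tissue[g] <- t
    }
    pair_truth <- data.frame(gene_a = character(), gene_b = character(),
                             expr_mode = character())
    pr <- pairs$pairs
    if (!is.null(pr) && nrow(pr) > 0) {
      modes <- config$duplicate_pair_spec$expr_mode %||%
        rep(c("contrasting", "contrasting", "contrasting",
              "contrasting", "contrasting", "shared"),
            length.out = nrow(pr))
      for (i in seq_len(nrow(pr))) {
        ga <- pr$gene_a[i]; gb <- pr$gene_b[i]
        if (!(ga %in% ids && gb %in% ids)) next
        if (modes[i] == "shared") {
          if (is.na(spec_tissue[ga])) {
            t <- sample(tissues, 1)
            m[ga, t] <- mu * stats::runif(1, 8, 12)
            spec_tissue[ga] <- t
          }
          m[gb, ] <- m[ga, ] * stats::runif(1, 0.8, 1.2) *
            stats::runif(k, 0.99, 1.01)
          spec_tissue[gb] <- spec_tissue[ga]
        } else {
          if (is.na(spec_tissue[ga])) {
            t <- sample(tissues, 1)
            m[ga, t] <- mu * stats::runif(1, 8, 12)
            spec_tissue[ga] <- t
          }
          t2 <- sample(setdiff(tissues, spec_tissue[ga]), 1)
          m[gb, ] <- mu * stats::runif(k, 0.8, 1.2)
          m[gb, t2] <- mu * stats::runif(1, 8, 12)
          spec_tissue[gb] <- t2
        }
      }
      pair_truth <- data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b,
                               expr_mode = modes[seq_len(nrow(pr))],
                               stringsAsFactors = FALSE)
    }
    structure(list(matrix = m,
                   truth = data.frame(gene_id = ids,
                                      specific_tissue = unname(spec_tissue[ids]),
                                      stringsAsFactors = FALSE),
                   pair_truth = pair_truth),
              class = "sim_expression")
  })
}

#' Generate a two-population diploid SNP panel
#'
#' One biallelic locus per row of `pop_spec`: diploid genotypes are drawn
#' binomially from the planted wild and cultivated alternate-allele
#' frequencies. When gene models are supplied, loci are positioned inside
#' them (alternating exonic and intronic placements) and the reference
#' allele of exonic loci matches the gene's CDS, so the coding effect of the
#' alternate allele is well defined.
#'
#' @param config a [sim_config()].
#' @param gene_models optional [generate_gene_coordinates()] result.
#' @return list of class `sim_populations`: `loci` (locus_id, chromosome,
#'   position, ref, alt, gene_id, context), `genotypes` (character matrix of
#'   GT strings, loci x samples), `pop_map` (sample, population) and `truth`
#'   (planted frequencies per locus).
#' @export
generate_populations <- function(config, gene_models = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ps <- config$pop_spec
  if (is.null(ps) || nrow(ps) == 0) {
    return(structure(list(loci = data.frame(), genotypes = NULL,
                          pop_map = data.frame(), truth = data.frame()),
                     class = "sim_populations"))
  }
  if (is.null(gene_models)) gene_models <- generate_gene_coordinates(config)
  with_rng(config$seed + 67L, {
    n_w <- as.integer(ps$n_wild[1]); n_c <- as.integer(ps$n_cult[1])
    samples <- c(sprintf("WILD%03d", seq_len(n_w)),
                 sprintf("CULT%03d", seq_len(n_c)))
    pop_map <- data.frame(sample = samples,
                          population = c(rep("wild", n_w), rep("cult", n_c)),
                          stringsAsFactors = FALSE)
    genes <- gene_models$genes
    placed <- genes[genes$chromosome != "scaffold_1" &
                      startsWith(genes$gene_id, "GmSYN"), , drop = FALSE]
    host_ok <- nrow(placed) > 0
    loci <- list(); gts <- list(); truth <- list()
    for (j in seq_len(nrow(ps))) {
      want_exon <- j %% 2 == 1
      if (host_ok) {
        g <- placed[(j - 1L) %% nrow(placed) + 1L, ]
        ex <- gene_models$exons[gene_models$exons$gene_id == g$gene_id, ]
        in_exon <- want_exon || nrow(ex) < 2
        if (in_exon) {
          # pick a CDS position away from the terminal stop codon
          cds_len <- sum(ex$end - ex$start + 1L)
          cds_pos <- sample(seq_len(cds_len - 3L), 1)
          gpos <- genomic_position_of_cds(cds_pos, ex, g$strand)
          cds_base <- substr(gene_models$cds_seq[[g$gene_id]], cds_pos, cds_pos)
          ref <- if (g$strand == "-") unname(complement_base(cds_base))
                 else cds_base
          ctx <- "exon"
        } else {
          introns <- data.frame(start = ex$end[-nrow(ex)] + 1L,
                                end = ex$start[-1L] - 1L)
          introns <- introns[introns$end >= introns$start, , drop = FALSE]
          row <- introns[sample(nrow(introns), 1), ]
          gpos <- sample(row$start:row$end, 1)
          ref <- sample(c("A", "C", "G", "T"), 1)
          ctx <- "intron"
        }
        chrom <- g$chromosome; gene_id <- g$gene_id
      } else {
        chrom <- "Chr01"; gpos <- j * 1000L
        ref <- sample(c("A", "C", "G", "T"), 1)
        ctx <- "outside"; gene_id <- NA_character_
      }
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      gw <- stats::rbinom(n_w, 2, ps$p_wild[j])
      gc <- stats::rbinom(n_c, 2, ps$p_cult[j])
      gt <- c(gw, gc)
      gt_str <- c("0/0", "0/1", "1/1")[gt + 1L]
      loci[[j]] <- data.frame(locus_id = sprintf("SNP%04d", j),
                              chromosome = chrom, position = gpos,
                              ref = ref, alt = alt, gene_id = gene_id,
                              context = ctx, stringsAsFactors = FALSE)
      gts[[j]] <- gt_str
      truth[[j]] <- data.frame(locus_id = sprintf("SNP%04d", j),
                               p_wild = ps$p_wild[j], p_cult = ps$p_cult[j],
                               stringsAsFactors = FALSE)
    }
    gt_mat <- do.call(rbind, gts)
    rownames(gt_mat) <- sprintf("SNP%04d", seq_len(nrow(ps)))
    colnames(gt_mat) <- samples
    structure(list(loci = do.call(rbind, loci),
                   genotypes = gt_mat,
                   pop_map = pop_map,
                   truth = do.call(rbind, truth)),
              class = "sim_populations")
  })
}
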