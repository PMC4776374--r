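# Selection scan: per-locus gene diversity in two populations, Fst (Nei GST
# or Weir-Cockerham 1984), threshold classification, coding-effect
# annotation through the gene model, and per-gene / per-population reports.

#' Gene diversity (expected heterozygosity) from allele counts
#'
#' `H = 1 - sum(p_i^2)` over observed allele frequencies; the unbiased
#' (Nei 1987) variant multiplies by `n / (n - 1)` with `n` the number of
#' sampled alleles.
#'
#' @param counts nonnegative per-allele counts (named or not).
#' @param unbiased apply the small-sample correction.
#' @return diversity value.
#' @export
gene_diversity <- function(counts, unbiased = FALSE) {
  n <- sum(counts)
  if (n < 1) stop("no alleles observed")
  if (unbiased && n < 2) stop("unbiased estimator needs n >= 2")
  p <- counts / n
  h <- 1 - sum(p^2)
  if (unbiased) h * n / (n - 1) else h
}

#' Fst between two populations at one locus
#'
#' `GST`: within-population diversities are averaged (`Hs`), total
#' diversity `Ht` is computed at the unweighted mean of the two frequency
#' vectors, and `Fst = (Ht - Hs) / Ht` (0 when `Ht = 0`). `WC84` is the
#' Weir & Cockerham (1984) theta-hat variance-components estimator computed
#' from allele counts and sample sizes; it can be slightly negative for
#' undifferentiated samples and is reported as-is.
#'
#' @param counts_wild,counts_cult per-allele counts (aligned by name when
#'   named, by position otherwise).
#' @param estimator `"gst"` or `"wc84"` (default `"wc84"`, matching what
#'   population genetics packages report).
#' @return Fst estimate; attribute `monomorphic` is TRUE when both samples
#'   share one fixed allele.
#' @export
fst <- function(counts_wild, counts_cult, estimator = c("wc84", "gst")) {
  estimator <- match.arg(estimator)
  if (!is.null(names(counts_wild)) && !is.null(names(counts_cult))) {
    alleles <- union(names(counts_wild), names(counts_cult))
    cw <- stats::setNames(rep(0, length(alleles)), alleles)
    cc <- cw
    cw[names(counts_wild)] <- counts_wild
    cc[names(counts_cult)] <- counts_cult
  } else {
    stopifnot(length(counts_wild) == length(counts_cult))
    cw <- counts_wild; cc <- counts_cult
  }
  n1 <- sum(cw); n2 <- sum(cc)
  if (n1 < 1 || n2 < 1) stop("both populations need at least one allele")
  p1 <- cw / n1; p2 <- cc / n2
  if (estimator == "gst") {
    hs <- (gene_diversity(cw) + gene_diversity(cc)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 1 - sum(pbar^2)
    out <- if (ht == 0) 0 else (ht - hs) / ht
    attr(out, "monomorphic") <- ht == 0
    return(out)
  }
  # Weir & Cockerham (1984), allele-count (haploid-sample) form, r = 2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  a_sum <- b_sum <- 0
  for (k in seq_along(cw)) {
    pb <- (n1 * p1[k] + n2 * p2[k]) / (n1 + n2)
    s2 <- (n1 * (p1[k] - pb)^2 + n2 * (p2[k] - pb)^2) / ((r - 1) * nbar)
    term <- pb * (1 - pb) - (r - 1) / r * s2
    if (nbar > 1) {
      a_k <- (nbar / nc) * (s2 - term / (nbar - 1))
      b_k <- (nbar / (nbar - 1)) * term
    } else {
      # single allele per population: only the between-population component
      # is estimable
      a_k <- (nbar / nc) * s2
      b_k <- 0
    }
    a_sum <- a_sum + a_k
    b_sum <- b_sum + b_k
  }
  mono <- a_sum + b_sum == 0
  out <- if (mono) 0 else a_sum / (a_sum + b_sum)
  out <- min(out, 1)
  attr(out, "monomorphic") <- mono
  out
}

#' Selection-scan thresholds
#'
#' @param fst_selected loci with Fst strictly above this are `selected`
#'   (default 0.45).
#' @param fst_neutral loci with Fst strictly below this are `non-selected`
#'   (default 0.15); in between is `intermediate`.
#' @param estimator Fst estimator passed to [fst()].
#' @return list of class `selection_params`.
#' @export
selection_params <- function(fst_selected = 0.45, fst_neutral = 0.15,
                             estimator = "wc84") {
  stopifnot(fst_neutral >= 0, fst_neutral < fst_selected, fst_selected <= 1)
  structure(list(fst_selected = fst_selected, fst_neutral = fst_neutral,
                 estimator = estimator), class = "selection_params")
}

# per-population alternate/reference allele counts from a GT matrix
allele_counts_by_pop <- function(genotypes, pop_map) {
  pops <- unique(pop_map$population)
  out <- list()
  for (p in pops) {
    smp <- pop_map$sample[pop_map$population == p]
    gt <- genotypes[, intersect(smp, colnames(genotypes)), drop = FALSE]
    cnt <- t(apply(gt, 1, function(row) {
      alleles <- unlist(strsplit(row, "[/|]"))
      alleles <- alleles[alleles %in% c("0", "1")]  # missing excluded
      c(ref = sum(alleles == "0"), alt = sum(alleles == "1"))
    }))
    out[[p]] <- cnt
  }
  out
}

#' Per-locus diversity and Fst scan over a genotype panel
#'
#' @param genotypes loci x samples matrix of GT strings (`0/0`, `0/1`,
#'   `1/1`, `./.`).
#' @param pop_map data frame (sample, population) with populations `wild`
#'   and `cult`.
#' @param params a [selection_params()].
#' @param unbiased use the unbiased diversity estimator.
#' @return data frame: locus_id, H_wild, H_cult, Fst.
#' @export
scan_loci <- function(genotypes, pop_map, params = selection_params(),
                      unbiased = FALSE) {
  cnt <- allele_counts_by_pop(genotypes, pop_map)
  stopifnot(all(c("wild", "cult") %in% names(cnt)))
  loci <- rownames(genotypes)
  data.frame(
    locus_id = loci,
    H_wild = vapply(seq_along(loci), function(i)
      gene_diversity(cnt$wild[i, ], unbiased), numeric(1)),
    H_cult = vapply(seq_along(loci), function(i)
      gene_diversity(cnt$cult[i, ], unbiased), numeric(1)),
    Fst = vapply(seq_along(loci), function(i)
      as.numeric(fst(cnt$wild[i, ], cnt$cult[i, ], params$estimator)),
      numeric(1)),
    stringsAsFactors = FALSE)
}

#' Classify scanned loci by Fst thresholds
#'
#' Strict boundaries follow the study definitions: `selected` means
#' `Fst > fst_selected`, `non-selected` means `Fst < fst_neutral`, the rest
#' is `intermediate`.
#'
#' @param results data frame with `locus_id`, `Fst` and optionally
#'   `gene_id`.
#' @param params a [selection_params()].
#' @return list with `loci` (input plus `class`), `summary` (class, n, pct)
#'   and, when gene ids are present, `selected_genes` (gene_id, n_snps).
#' @export
classify_loci <- function(results, params = selection_params()) {
  cls <- ifelse(results$Fst > params$fst_selected, "selected",
                ifelse(results$Fst < params$fst_neutral, "non-selected",
                       "intermediate"))
  results$class <- cls
  n <- nrow(results)
  lev <- c("selected", "intermediate", "non-selected")
  summary <- data.frame(
    class = lev,
    n = vapply(lev, function(l) sum(cls == l), integer(1)),
    pct = vapply(lev, function(l) percentage(sum(cls == l), n), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  out <- list(loci = results, summary = summary)
  if (!is.null(results$gene_id)) {
    sel <- results[cls == "selected" & !is.na(results$gene_id), ]
    if (nrow(sel)) {
      tab <- table(sel$gene_id)
      out$selected_genes <- data.frame(gene_id = names(tab),
                                       n_snps = as.integer(tab),
                                       stringsAsFactors = FALSE)
    } else {
      out$selected_genes <- data.frame(gene_id = character(),
                                       n_snps = integer())
    }
  }
  out
}

#' Coding effect of a SNP through its gene model
#'
#' Maps the genomic position through the gene's CDS spans (respecting
#' strand; alleles are complemented on `-`), substitutes the alternate
#' allele into the affected codon and translates: same amino acid is
#' `synonymous`, a change is `nonsynonymous`. Positions between exons are
#' `intronic`; positions inside the gene but outside the CDS are `outside`.
#'
#' @param position genomic position (1-based).
#' @param ref,alt single-nucleotide alleles as they appear on the genome.
#' @param gene one row of a gene table (gene_id, start, end, strand).
#' @param cds_spans data frame of the gene's CDS genomic intervals.
#' @param cds_seq the gene's CDS sequence (transcription orientation).
#' @return one of "synonymous", "nonsynonymous", "intronic", "outside";
#'   attributes `codon`, `codon_alt` and `aa`/`aa_alt` for coding calls.
#' @export
annotate_effect <- function(position, ref, alt, gene, cds_spans, cds_seq) {
  if (nchar(ref) != 1 || nchar(alt) != 1)
    stop("only single-nucleotide alleles are supported")
  if (position < gene$start || position > gene$end)
    stop("position outside gene span")
  cds_spans <- cds_spans[order(cds_spans$start), ]
  cpos <- cds_position_of_genomic(position, cds_spans, gene$strand)
  if (is.na(cpos)) {
    # inside the gene: intron if between two CDS/exon spans, else outside
    introns_lo <- cds_spans$end[-nrow(cds_spans)] + 1L
    introns_hi <- cds_spans$start[-1L] - 1L
    if (length(introns_lo) &&
        any(position >= introns_lo & position <= introns_hi))
      return("intronic")
    return("outside")
  }
  ref_t <- if (gene$strand == "-") unname(complement_base(ref)) else ref
  alt_t <- if (gene$strand == "-") unname(complement_base(alt)) else alt
  have <- substr(cds_seq, cpos, cpos)
  if (have != ref_t)
    warning("reference allele disagrees with CDS base at position ",
            position, " (", have, " vs ", ref_t, ")")
  ci <- (cpos - 1L) %/% 3L
  off <- (cpos - 1L) %% 3L + 1L
  codon <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
  codon_alt <- codon
  substr(codon_alt, off, off) <- alt_t
  aa <- translate_codon(codon)
  aa_alt <- translate_codon(codon_alt)
  out <- if (aa == aa_alt) "synonymous" else "nonsynonymous"
  attr(out, "codon") <- codon
  attr(out, "codon_alt") <- codon_alt
  attr(out, "aa") <- aa
  attr(out, "aa_alt") <- aa_alt
  out
}

#' Population diversity report
#'
#' @param results data frame with `H_wild` and `H_cult` (>= 1 row).
#' @return list with `means` (per population, 2 decimals) and `histogram`
#'   (bins of width 0.1 over `[0, 1]`, counts per population).
#' @export
diversity_report <- function(results) {
  if (nrow(results) < 1) stop("no loci")
  if (any(is.na(results$H_wild)) || any(is.na(results$H_cult)))
    stop("missing diversity values")
  breaks <- (0:10) / 10  # exact decimal representations for the bin edges
  bin <- function(h) {
    idx <- findInterval(h, breaks, rightmost.closed = TRUE)
    tabulate(idx, nbins = 10)
  }
  list(means = c(wild = round_half_away(mean(results$H_wild), 2),
                 cult = round_half_away(mean(results$H_cult), 2)),
       histogram = data.frame(bin_low = breaks[-11], bin_high = breaks[-1],
                              wild = bin(results$H_wild),
                              cult = bin(results$H_cult)))
}
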