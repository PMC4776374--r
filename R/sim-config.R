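#' Simulation configuration for the synthetic input generator
#'
#' Builds the single configuration object consumed by every generator in the
#' synthetic-data module. Defaults emulate the structure of the soybean
#' LRR-RLK study system at desk scale: 20 chromosomes, a family whose
#' proteins span 423-1563 residues, tandem clusters within a 200-kb window,
#' paralog pairs whose synonymous divergence sits on the two
#' whole-genome-duplication Ks peaks (~0.15 and ~0.57), a nine-tissue
#' expression atlas, and a 21-wild / 35-cultivated diploid SNP panel whose
#' planted allele frequencies give mean gene diversities of ~0.36 (wild) and
#' ~0.25 (cultivated) with a small high-Fst selected fraction.
#'
#' @param seed integer random seed; the same config and seed give
#'   byte-identical outputs.
#' @param n_family count of true family genes (>= 1 LRR and >= 1 kinase
#'   domain each).
#' @param n_decoy count of non-family genes, cycled over the three decoy
#'   classes `lrr_only`, `kinase_only`, `neither`.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length chromosome length in bp.
#' @param n_groups number of phylogenetic groups planted in the kinase
#'   domains (within-group divergence far below between-group).
#' @param n_refs_per_group reference (outgroup genome) proteins per group,
#'   used for group-label transfer and as prescreen queries.
#' @param tandem_cluster_spec data frame with columns `chromosome` (integer),
#'   `n` (members) and `spacing` (start-to-start bp); spacing must be at or
#'   below the tandem window for an intended cluster.
#' @param tandem_window bp window used when spacing non-cluster genes
#'   (they are placed strictly further apart than this).
#' @param n_unplaced number of family genes assigned to an unanchored
#'   scaffold instead of a chromosome.
#' @param duplicate_pair_spec data frame describing paralog pairs; either
#'   integer columns `sd` and `nd` (planted synonymous / nonsynonymous
#'   differences) or `target_ks` / `target_ka` (converted to counts from the
#'   ancestral sequence's site totals), plus codon length `L`.
#' @param n_tissues number of expression atlas tissues (>= 2).
#' @param specificity_fraction fraction of genes planted with one dominant
#'   tissue (mean at least 8x background).
#' @param pop_spec data frame with one row per SNP locus: `p_wild`, `p_cult`
#'   alternate-allele frequencies and diploid sample sizes `n_wild`,
#'   `n_cult`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_family = 80L,
                       n_decoy = 40L,
                       n_chromosomes = 20L,
                       chromosome_length = 5e7,
                       n_groups = 3L,
                       n_refs_per_group = 2L,
                       tandem_cluster_spec = default_tandem_spec(),
                       tandem_window = 2e5,
                       n_unplaced = 0L,
                       duplicate_pair_spec = default_pair_spec(),
                       n_tissues = 9L,
                       specificity_fraction = 0.8,
                       pop_spec = default_pop_spec()) {
  stopifnot(n_family >= 0, n_decoy >= 0, n_chromosomes >= 1,
            chromosome_length > 0, n_groups >= 1, n_tissues >= 2,
            specificity_fraction >= 0, specificity_fraction <= 1,
            tandem_window > 0, n_unplaced >= 0)
  if (nrow(pop_spec) > 0) {
    stopifnot(all(pop_spec$p_wild >= 0 & pop_spec$p_wild <= 1),
              all(pop_spec$p_cult >= 0 & pop_spec$p_cult <= 1),
              all(pop_spec$n_wild >= 1), all(pop_spec$n_cult >= 1))
  }
  if (nrow(tandem_cluster_spec) > 0) {
    stopifnot(all(tandem_cluster_spec$n >= 2),
              all(tandem_cluster_spec$spacing > 0))
    if (sum(tandem_cluster_spec$n) > n_family)
      stop("tandem_cluster_spec requests more genes than n_family")
  }
  structure(list(
    seed = as.integer(seed),
    n_family = as.integer(n_family),
    n_decoy = as.integer(n_decoy),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    n_groups = as.integer(n_groups),
    n_refs_per_group = as.integer(n_refs_per_group),
    tandem_cluster_spec = tandem_cluster_spec,
    tandem_window = tandem_window,
    n_unplaced = as.integer(n_unplaced),
    duplicate_pair_spec = duplicate_pair_spec,
    n_tissues = as.integer(n_tissues),
    specificity_fraction = specificity_fraction,
    pop_spec = pop_spec
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_family, "family +", x$n_decoy,
      "decoy genes on", x$n_chromosomes, "chromosomes |",
      nrow(x$tandem_cluster_spec), "tandem clusters |",
      nrow(x$duplicate_pair_spec), "duplicate pairs |",
      x$n_tissues, "tissues |", nrow(x$pop_spec), "SNP loci\n")
  invisible(x)
}

#' Default planted tandem-cluster layout
#'
#' Four clusters (10 + 3 + 2 + 2 genes, spacings within the 200-kb window)
#' so roughly a fifth of an 80-gene family is tandem-clustered, echoing the
#' 94-of-464 proportion and the 10-member largest cluster of the soybean
#' family.
#' @return data frame with columns `chromosome`, `n`, `spacing`.
#' @export
default_tandem_spec <- function() {
  data.frame(chromosome = c(16L, 18L, 2L, 8L),
             n = c(10L, 3L, 2L, 2L),
             spacing = c(150000, 80000, 120000, 150000))
}

#' Default planted paralog-pair divergences
#'
#' Thirty pairs of 300 codons: eighteen at the recent whole-genome
#' duplication Ks peak (~0.15), nine at the older peak (~0.57) and three
#' nearly undiverged, with Ka targets putting about three quarters of pairs
#' under omega < 0.3 (purifying) and the rest above.
#' @return data frame with columns `target_ks`, `target_ka`, `L`.
#' @export
default_pair_spec <- function() {
  ks <- c(rep(0.15, 18), rep(0.57, 9), rep(0.03, 3))
  omega <- c(rep(c(0.1, 0.1, 0.1, 0.45), length.out = 27), rep(0.1, 3))
  data.frame(target_ks = ks, target_ka = ks * omega, L = 300L)
}

#' Default two-population SNP panel
#'
#' 96 "neutral" loci whose planted frequencies give expected gene
#' diversities of 0.36 (wild) and 0.25 (cultivated), plus 4 strongly
#' differentiated loci (population-level GST about 0.87), sampled as 21 wild
#' and 35 cultivated diploid individuals.
#' @param n_neutral,n_selected locus counts per class.
#' @param n_wild,n_cult diploid sample sizes.
#' @return data frame with one row per locus.
#' @export
default_pop_spec <- function(n_neutral = 96L, n_selected = 4L,
                             n_wild = 21L, n_cult = 35L) {
  # 2p(1-p) = H  =>  p = (1 - sqrt(1 - 2H)) / 2
  p_w <- (1 - sqrt(1 - 2 * 0.36)) / 2
  p_c <- (1 - sqrt(1 - 2 * 0.25)) / 2
  data.frame(
    p_wild = c(rep(p_w, n_neutral), rep(0.95, n_selected)),
    p_cult = c(rep(p_c, n_neutral), rep(0.02, n_selected)),
    n_wild = n_wild,
    n_cult = n_cult
  )
}
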