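# Pipeline driver: chains identify -> phylo -> duplication -> kaks ->
# express -> select over a key-value config (YAML file or R list), skipping
# stages whose inputs are absent, and writes every artifact with a manifest
# of parameter values and input checksums.

default_pipeline_params <- function() {
  list(evalue = 1e-6,
       window = 200000,
       lambda = 6.1e-9,
       ks_bin_width = 0.06,
       ks_max = 1.02,
       omega_cutoff = 0.3,
       fold = 2,
       floor = 1,
       r_threshold = 0.8,
       fst_selected = 0.45,
       fst_neutral = 0.15,
       estimator = "wc84",
       distance_model = "p-distance",
       bootstrap = 1000,
       bootstrap_max_leaves = 60,
       seed = 1)
}

#' Run the full family-analysis pipeline
#'
#' @param config path to a YAML config file or an equivalent list, with
#'   elements `inputs` (paths: proteins, domains, optionally queries,
#'   kinase_alignment, ref_groups, gff, gene_cds, pairs, pairs_cds,
#'   expression, vcf, pop_map), `params` (any of the stage parameters; see
#'   the vignette) and `outdir`.
#' @return invisible report list; all tables, the Newick trees and
#'   `manifest.json` / `report.json` are written under `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs %||% list()
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(outdir, f)

  have <- function(key) !is.null(inputs[[key]]) && file.exists(inputs[[key]])
  manifest <- list(params = params, inputs = list(), stages = list())
  note <- function(stage, status, detail = NULL) {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
    message("[famevol] ", stage, ": ", status,
            if (!is.null(detail)) paste0(" (", detail, ")") else "")
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  for (key in names(inputs)) {
    if (file.exists(inputs[[key]]))
      manifest$inputs[[key]] <- list(path = inputs[[key]],
                                     md5 = unname(tools::md5sum(inputs[[key]])))
  }
  report <- list()

  # --- identify --------------------------------------------------------
  roster <- NULL
  if (have("proteins") && have("domains")) run_stage("identify", {
    proteins <- Biostrings::readAAStringSet(inputs$proteins)
    ann <- read_tsv(inputs$domains)
    prescreen <- NULL
    if (have("queries")) {
      queries <- Biostrings::readAAStringSet(inputs$queries)
      prescreen <- prescreen_by_similarity(proteins, queries,
                                           params$evalue)
      proteins <- proteins[attr(prescreen, "kept")]
      ann <- ann[ann$gene_id %in% names(proteins), , drop = FALSE]
      write_tsv(prescreen, op("prescreen.tsv"))
    }
    roster <- filter_by_domains(proteins, ann)
    write_tsv(roster, op("roster.tsv"))
    report$identify <- list(n_candidates = length(proteins),
                             n_members = nrow(roster))
    note("identify", "done", paste(nrow(roster), "family members"))
  }) else note("identify", "skipped", "proteins/domains missing")

  # --- phylo -----------------------------------------------------------
  assignments <- NULL
  if (have("kinase_alignment") && have("ref_groups")) run_stage("phylo", {
    aln <- Biostrings::readAAStringSet(inputs$kinase_alignment)
    refs <- read_tsv(inputs$ref_groups)
    if (!is.null(roster))
      aln <- aln[names(aln) %in% c(roster$gene_id, refs$gene_id)]
    dm <- kinase_distance_matrix(aln, params$distance_model)
    tree <- neighbor_joining(dm)
    ape::write.tree(clamp_branch_lengths(tree), op("tree.nwk"))
    # bootstrap on a subtree when the family is large
    boot_names <- names(aln)
    if (length(boot_names) > params$bootstrap_max_leaves)
      boot_names <- sort(boot_names)[seq_len(params$bootstrap_max_leaves)]
    bs <- bootstrap_support(aln[boot_names], n_reps = params$bootstrap,
                            seed = params$seed, model = params$distance_model)
    ape::write.tree(clamp_branch_lengths(bs$tree), op("tree_bootstrap.nwk"))
    ag <- assign_groups(tree, refs)
    assignments <- ag$assignments
    write_tsv(ag$assignments, op("group_assignments.tsv"))
    write_tsv(ag$monophyly, op("group_monophyly.tsv"))
    if (!is.null(roster)) {
      roster$subgroup <- assignments$group[
        match(roster$gene_id, assignments$gene_id)]
      write_tsv(roster, op("roster.tsv"))
    }
    report$phylo <- list(n_leaves = length(aln),
                          n_groups = length(unique(ag$assignments$group)),
                          mean_support = mean(bs$support$support))
    note("phylo", "done", paste(length(aln), "leaves"))
  }) else note("phylo", "skipped", "alignment/reference labels missing")

  # --- duplication -----------------------------------------------------
  gm <- NULL
  clusters <- NULL
  classified <- NULL
  if (have("gff")) run_stage("duplication", {
    gm <- read_gff3(inputs$gff)
    fam_genes <- if (!is.null(roster))
      gm$genes[gm$genes$gene_id %in% roster$gene_id, , drop = FALSE]
      else gm$genes
    dist <- chromosome_distribution(fam_genes)
    write_tsv(dist$distribution, op("chromosome_distribution.tsv"))
    clusters <- tandem_clusters(fam_genes, params$window)
    write_tsv(clusters$clusters, op("tandem_clusters.tsv"))
    report$duplication <- list(
      n_placed = dist$n_placed, n_unplaced = dist$n_unplaced,
      n_clusters = clusters$n_clusters,
      n_clustered_genes = clusters$n_clustered_genes,
      pct_clustered = if (dist$n_placed > 0)
        percentage(clusters$n_clustered_genes, dist$n_placed) else NA_real_)
    if (have("pairs")) {
      pairs <- read_tsv(inputs$pairs)
      classified <- classify_pairs(pairs, gm, clusters)
      write_tsv(classified, op("pairs_classified.tsv"))
      report$duplication$n_pairs <- nrow(classified)
      report$duplication$pct_segmental_genes <-
        attr(classified, "pct_segmental_genes")
    }
    note("duplication", "done",
         paste(clusters$n_clusters, "tandem clusters"))
  }) else note("duplication", "skipped", "gff missing")

  # --- kaks ------------------------------------------------------------
  kaks <- NULL
  if (have("pairs") && have("pairs_cds")) run_stage("kaks", {
    pairs <- read_tsv(inputs$pairs)
    cds <- Biostrings::readDNAStringSet(inputs$pairs_cds)
    ep <- evol_params(lambda_rate = params$lambda,
                      omega_cutoff = params$omega_cutoff,
                      ks_bin_width = params$ks_bin_width,
                      ks_max = params$ks_max)
    kaks <- compute_kaks_pairs(cds, pairs, ep)
    if (!is.null(classified))
      kaks$mode <- classified$mode[match(
        paste(kaks$gene_a, kaks$gene_b),
        paste(classified$gene_a, classified$gene_b))]
    write_tsv(kaks, op("kaks.tsv"))
    kh <- ks_histogram(kaks, ep)
    write_tsv(kh$histogram, op("ks_histogram.tsv"))
    om <- categorize_omega(kaks, ep)
    report$kaks <- list(
      n_pairs = nrow(kaks),
      ks_range = range(kaks$Ks, na.rm = TRUE),
      age_range_my = range(kaks$age_my, na.rm = TRUE),
      peaks = kh$peaks,
      n_omega_below = om$n_below,
      n_omega_at_or_above = om$n_at_or_above)
    note("kaks", "done", paste(nrow(kaks), "pairs"))
  }) else note("kaks", "skipped", "pairs/pairs_cds missing")

  # --- express ---------------------------------------------------------
  if (have("expression")) run_stage("express", {
    m <- read_expression_tsv(inputs$expression)
    norm <- genewise_normalize(m)
    hc <- hierarchical_cluster(norm)
    ape::write.tree(ape::as.phylo(hc), op("expression_dendrogram.nwk"))
    pref <- tissue_preference(m, params$fold, params$floor)
    write_tsv(pref$counts, op("tissue_preference_counts.tsv"))
    report$express <- list(n_genes = nrow(m), n_tissues = ncol(m),
                            tissue_counts = pref$counts)
    if (have("pairs")) {
      pairs <- read_tsv(inputs$pairs)
      div <- duplicate_expression_divergence(
        pairs, m, params$r_threshold,
        clusters = if (!is.null(clusters)) clusters$clusters else NULL)
      write_tsv(div$pairs, op("pair_expression_divergence.tsv"))
      report$express$n_pairs_similar <- div$n_similar
      report$express$n_pairs_divergent <- div$n_divergent
      if (!is.null(div$clusters)) {
        write_tsv(div$clusters, op("cluster_expression_divergence.tsv"))
        report$express$n_clusters_similar <-
          sum(div$clusters$call == "similar")
      }
    }
    note("express", "done", paste(nrow(m), "genes"))
  }) else note("express", "skipped", "expression matrix missing")

  # --- select ----------------------------------------------------------
  if (have("vcf") && have("pop_map")) run_stage("select", {
    panel <- read_vcf(inputs$vcf)
    pop_map <- read_tsv(inputs$pop_map)
    sp <- selection_params(params$fst_selected, params$fst_neutral,
                           params$estimator)
    res <- scan_loci(panel$genotypes, pop_map, sp)
    res$gene_id <- panel$loci$gene_id[match(res$locus_id,
                                            panel$loci$locus_id)]
    cl <- classify_loci(res, sp)
    # coding effect of selected loci, when gene models and CDS are at hand
    if (!is.null(gm) && have("gene_cds")) {
      cds_set <- Biostrings::readDNAStringSet(inputs$gene_cds)
      eff <- vapply(seq_len(nrow(cl$loci)), function(i) {
        row <- cl$loci[i, ]
        li <- panel$loci[panel$loci$locus_id == row$locus_id, ]
        if (is.na(li$gene_id) || !(li$gene_id %in% gm$genes$gene_id) ||
            !(li$gene_id %in% names(cds_set)))
          return(NA_character_)
        g <- gm$genes[gm$genes$gene_id == li$gene_id, ]
        spn <- gm$cds_spans[gm$cds_spans$gene_id == li$gene_id, ]
        as.character(annotate_effect(li$position, li$ref, li$alt, g, spn,
                                     as.character(cds_set[[li$gene_id]])))
      }, character(1))
      cl$loci$effect <- eff
    }
    write_tsv(cl$loci, op("selection_loci.tsv"))
    write_tsv(cl$summary, op("selection_summary.tsv"))
    if (!is.null(cl$selected_genes))
      write_tsv(cl$selected_genes, op("selected_genes.tsv"))
    dr <- diversity_report(cl$loci)
    write_tsv(dr$histogram, op("diversity_histogram.tsv"))
    report$select <- list(n_loci = nrow(cl$loci),
                           summary = cl$summary,
                           mean_H = dr$means,
                           n_selected_genes =
                             if (!is.null(cl$selected_genes))
                               nrow(cl$selected_genes) else NA_integer_)
    note("select", "done", paste(nrow(cl$loci), "loci"))
  }) else note("select", "skipped", "vcf/pop_map missing")

  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  jsonlite::write_json(report, op("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "columns")
  invisible(report)
}
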