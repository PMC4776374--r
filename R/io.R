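# File interchange: VCF 4.2 and expression TSV, plus the one-call writer
# that materializes a full synthetic input bundle.

#' Write a two-population SNP panel as VCF 4.2
#'
#' @param pops a `sim_populations` object (or a list with `loci` and
#'   `genotypes` of the same shape).
#' @param path output VCF file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(pops, path) {
  loci <- pops$loci
  gt <- pops$genotypes
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famevol-simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$chromosome[i], loci$position[i], loci$locus_id[i],
            loci$ref[i], loci$alt[i], ".", "PASS",
            if (is.na(loci$gene_id[i])) "." else
              paste0("GENE=", loci$gene_id[i], ";CTX=", loci$context[i]),
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF 4.2 SNP panel
#'
#' Thin wrapper over [vcfR::read.vcfR()] returning the locus table and GT
#' matrix used by the selection-scan module.
#'
#' @param path VCF file.
#' @return list with `loci` (locus_id, chromosome, position, ref, alt,
#'   gene_id, context) and `genotypes` (loci x samples GT strings).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  loci <- data.frame(locus_id = fix$ID,
                     chromosome = fix$CHROM,
                     position = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     gene_id = grab("GENE"), context = grab("CTX"),
                     stringsAsFactors = FALSE)
  rownames(gt) <- loci$locus_id
  list(loci = loci, genotypes = gt)
}

#' Write / read an expression matrix TSV (genes x named tissues)
#'
#' @param m numeric matrix with gene rownames and tissue colnames.
#' @param path TSV file.
#' @return `path` invisibly (writer); numeric matrix (reader).
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Materialize a complete synthetic input bundle
#'
#' Runs every generator for one configuration and writes all pipeline inputs
#' to `dir`: proteins and reference proteins (FASTA), domain annotations
#' (TSV), gene models (GFF3) with per-gene CDS (FASTA), the precomputed
#' kinase-domain alignment (FASTA; domains are fixed-length so extraction is
#' the alignment), reference group labels (TSV), paralog pairs (TSV) with
#' their CDS (FASTA), the expression atlas (TSV), the SNP panel (VCF 4.2)
#' with its population map (TSV), and all planted truth as JSON.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list with the generated objects and file `paths`.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  prot <- generate_proteome(config)
  gm <- generate_gene_coordinates(config, prot)
  pairs <- generate_duplicate_pairs(config)
  expr <- generate_expression(config, prot, pairs)
  pops <- generate_populations(config, gm)

  Biostrings::writeXStringSet(prot$proteins, p("proteins.faa"))
  Biostrings::writeXStringSet(prot$reference, p("reference.faa"))
  write_tsv(prot$annotations, p("domains.tsv"))
  write_tsv(prot$ref_groups, p("ref_groups.tsv"))
  write_gff3(gm, p("genes.gff3"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gm$cds_seq),
                              p("gene_cds.fna"))

  # kinase-domain "alignment": family + reference kinase domains, all the
  # same fixed length by construction
  tr <- prot$truth
  fam <- tr[tr$is_family, ]
  kin <- character(0)
  for (i in seq_len(nrow(fam)))
    kin[fam$gene_id[i]] <- substr(as.character(prot$proteins[[fam$gene_id[i]]]),
                                  fam$kinase_start[i], fam$kinase_end[i])
  rk <- prot$ref_kinase
  for (i in seq_len(nrow(rk)))
    kin[rk$gene_id[i]] <- substr(as.character(prot$reference[[rk$gene_id[i]]]),
                                 rk$kinase_start[i], rk$kinase_end[i])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(kin),
                              p("kinase_alignment.faa"))

  if (nrow(pairs$pairs)) {
    write_tsv(pairs$pairs, p("pairs.tsv"))
    Biostrings::writeXStringSet(pairs$cds, p("pairs_cds.fna"))
  }
  write_expression_tsv(expr$matrix, p("expression.tsv"))
  if (nrow(pops$loci)) {
    write_vcf(pops, p("snps.vcf"))
    write_tsv(pops$pop_map, p("pop_map.tsv"))
  }

  truth <- list(proteome = prot$truth,
                clusters = gm$truth_clusters,
                pairs = pairs$truth,
                expression = expr$truth,
                expression_pairs = expr$pair_truth,
                populations = pops$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       digits = NA, na = "null")

  invisible(list(config = config, proteome = prot, gene_models = gm,
                 pairs = pairs, expression = expr, populations = pops,
                 truth = truth,
                 paths = list(
                   proteins = p("proteins.faa"),
                   reference = p("reference.faa"),
                   domains = p("domains.tsv"),
                   ref_groups = p("ref_groups.tsv"),
                   gff = p("genes.gff3"),
                   gene_cds = p("gene_cds.fna"),
                   kinase_alignment = p("kinase_alignment.faa"),
                   pairs = p("pairs.tsv"),
                   pairs_cds = p("pairs_cds.fna"),
                   expression = p("expression.tsv"),
                   vcf = p("snps.vcf"),
                   pop_map = p("pop_map.tsv"),
                   truth = p("truth.json"))))
}
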