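test_that("proteome generator plants the membership criterion and is deterministic", {
  cfg <- sim_config(seed = 1, n_family = 10, n_decoy = 6,
                    tandem_cluster_spec = data.frame(),
                    duplicate_pair_spec = data.frame(),
                    pop_spec = data.frame())
  pr <- generate_proteome(cfg)
  expect_length(pr$proteins, 16)
  expect_equal(sum(pr$truth$is_family), 10)

  fam <- pr$truth$gene_id[pr$truth$is_family]
  for (id in fam) {
    ann <- pr$annotations[pr$annotations$gene_id == id, ]
    expect_gte(sum(ann$domain_type == "LRR"), 1)
    expect_gte(sum(ann$domain_type == "kinase"), 1)
  }
  # family protein lengths within the reported 423-1563 range
  expect_true(all(pr$truth$length[pr$truth$is_family] >= 423))
  expect_true(all(pr$truth$length[pr$truth$is_family] <= 1563))

  # decoys miss at least one criterion, across three classes
  dec <- pr$truth[!pr$truth$is_family, ]
  expect_setequal(unique(dec$decoy_class),
                  c("lrr_only", "kinase_only", "neither"))
  for (id in dec$gene_id) {
    ann <- pr$annotations[pr$annotations$gene_id == id, ]
    expect_true(sum(ann$domain_type == "LRR") == 0 ||
                  sum(ann$domain_type == "kinase") == 0)
  }

  # byte-identical reruns
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  Biostrings::writeXStringSet(generate_proteome(cfg)$proteins,
                              file.path(d1, "p.faa"))
  Biostrings::writeXStringSet(generate_proteome(cfg)$proteins,
                              file.path(d2, "p.faa"))
  expect_identical(readLines(file.path(d1, "p.faa")),
                   readLines(file.path(d2, "p.faa")))

  # empty config gives empty outputs, not failure
  empty <- generate_proteome(sim_config(n_family = 0, n_decoy = 0,
                                        tandem_cluster_spec = data.frame(),
                                        duplicate_pair_spec = data.frame(),
                                        pop_spec = data.frame()))
  expect_length(empty$proteins, 0)
})

test_that("gene coordinates respect planted spacings and report infeasibility", {
  cfg <- small_config(seed = 2)
  gm <- generate_gene_coordinates(cfg)
  cl <- gm$truth_clusters
  expect_equal(nrow(cl), 3)
  starts <- gm$genes$start[match(cl$gene_id, gm$genes$gene_id)]
  expect_equal(diff(sort(starts)), c(150000, 150000))
  expect_true(all(gm$genes$start <= gm$genes$end))

  # non-cluster genes sit further apart than the window on every chromosome
  non <- gm$genes[!(gm$genes$gene_id %in% cl$gene_id), ]
  for (ch in unique(non$chromosome)) {
    s <- sort(non$start[non$chromosome == ch])
    if (length(s) > 1) expect_true(all(diff(s) > cfg$tandem_window))
  }

  # infeasible request errors and names the chromosome
  bad <- sim_config(seed = 1, n_family = 12, n_decoy = 0,
                    n_chromosomes = 3, chromosome_length = 5e6,
                    tandem_cluster_spec = data.frame(chromosome = 2L,
                                                     n = 10L,
                                                     spacing = 1e6),
                    duplicate_pair_spec = data.frame(),
                    pop_spec = data.frame())
  expect_error(generate_gene_coordinates(bad), "chromosome 2")
})

test_that("duplicate pairs carry exactly the planted edits and never a stop", {
  cfg <- small_config(seed = 3)
  pp <- generate_duplicate_pairs(cfg)
  expect_equal(nrow(pp$truth), 3)

  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(pp$truth))) {
    a <- as.character(pp$cds[[pp$truth$gene_a[i]]])
    b <- as.character(pp$cds[[pp$truth$gene_b[i]]])
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    expect_false(any(code[ca] == "*"))
    expect_false(any(code[cb] == "*"))
    ndiff_nt <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(ndiff_nt, pp$truth$sd_true[i] + pp$truth$nd_true[i])
    # each differing codon differs at exactly one site, with the planted
    # synonymous/nonsynonymous split
    d <- which(ca != cb)
    syn <- sum(code[ca[d]] == code[cb[d]])
    expect_equal(syn, pp$truth$sd_true[i])
    expect_equal(length(d) - syn, pp$truth$nd_true[i])
  }
  # sd = nd = 0 gives identical sequences
  expect_identical(as.character(pp$cds[[pp$truth$gene_a[2]]]),
                   as.character(pp$cds[[pp$truth$gene_b[2]]]))
})

test_that("expression generator plants recoverable tissue specificity", {
  cfg <- small_config(seed = 4)
  ex <- generate_expression(cfg)
  expect_true(all(ex$matrix >= 0))
  spec <- ex$truth[!is.na(ex$truth$specific_tissue), ]
  for (i in seq_len(nrow(spec))) {
    row <- ex$matrix[spec$gene_id[i], ]
    expect_equal(names(which.max(row)), spec$specific_tissue[i])
  }
  expect_identical(generate_expression(cfg)$matrix, ex$matrix)
})

test_that("population generator hits its closed-form and large-sample targets", {
  cfg <- small_config(seed = 5)
  pop <- generate_populations(cfg)
  gt <- pop$genotypes
  # p_wild = p_cult = 0: everyone homozygous reference
  expect_true(all(gt["SNP0001", ] == "0/0"))
  # fixed difference
  wild <- pop$pop_map$sample[pop$pop_map$population == "wild"]
  cult <- pop$pop_map$sample[pop$pop_map$population == "cult"]
  expect_true(all(gt["SNP0002", wild] == "1/1"))
  expect_true(all(gt["SNP0002", cult] == "0/0"))

  # binomial concentration at n = 500
  big <- sim_config(seed = 6, n_family = 4, n_decoy = 0,
                    tandem_cluster_spec = data.frame(),
                    duplicate_pair_spec = data.frame(),
                    pop_spec = data.frame(p_wild = 0.9, p_cult = 0.1,
                                          n_wild = 500L, n_cult = 500L))
  bp <- generate_populations(big)
  count_alt <- function(cells) {
    al <- unlist(strsplit(cells, "/"))
    mean(al == "1")
  }
  expect_lt(abs(count_alt(bp$genotypes[1, sprintf("WILD%03d", 1:500)]) - 0.9),
            0.05)
  expect_lt(abs(count_alt(bp$genotypes[1, sprintf("CULT%03d", 1:500)]) - 0.1),
            0.05)
})

test_that("written truth labels round-trip through the bundle", {
  cfg <- small_config(seed = 7)
  dir <- withr::local_tempdir()
  bundle <- simulate_inputs(cfg, dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$proteome$gene_id, bundle$proteome$truth$gene_id)
  expect_equal(truth$proteome$is_family, bundle$proteome$truth$is_family)
  expect_equal(truth$clusters$gene_id, bundle$gene_models$truth_clusters$gene_id)
  expect_equal(truth$pairs$sd_true, bundle$pairs$truth$sd_true)
  expect_equal(truth$populations$p_wild, bundle$populations$truth$p_wild)
})
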