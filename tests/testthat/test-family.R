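test_that("similarity prescreen keeps self-hits and rejects random decoys", {
  cfg <- sim_config(seed = 11, n_family = 6, n_decoy = 3,
                    tandem_cluster_spec = data.frame(),
                    duplicate_pair_spec = data.frame(),
                    pop_spec = data.frame())
  pr <- generate_proteome(cfg)
  queries <- pr$reference
  # a verbatim copy of a query among the candidates is always retained
  cands <- c(pr$proteins,
             Biostrings::AAStringSet(c(SELF = as.character(queries[[1]]))))
  res <- prescreen_by_similarity(cands, queries, 1e-6)
  expect_true(res$keep[res$gene_id == "SELF"])
  # family members share the planted kinase ancestors with the references
  fam <- pr$truth$gene_id[pr$truth$is_family]
  expect_true(all(res$keep[res$gene_id %in% fam]))

  # a random-composition decoy scores like noise: E-value far above 1e-6,
  # confirmed by recomputing E from the alignment score directly
  set.seed(1)
  decoy <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        400, replace = TRUE), collapse = "")
  res2 <- prescreen_by_similarity(
    Biostrings::AAStringSet(c(RAND = decoy)), queries, 1e-6)
  expect_false(res2$keep[1])
  s <- max(vapply(seq_along(queries), function(i)
    Biostrings::pairwiseAlignment(decoy, queries[[i]], type = "local",
                                  substitutionMatrix = "BLOSUM62",
                                  gapOpening = 11, gapExtension = 1,
                                  scoreOnly = TRUE), numeric(1)))
  e_direct <- 0.041 * 400 * sum(Biostrings::width(queries)) * exp(-0.267 * s)
  expect_equal(res2$evalue[1], e_direct, tolerance = 1e-9)
  expect_gt(e_direct, 1e-6)

  # infinite threshold is a vacuous filter
  res3 <- prescreen_by_similarity(pr$proteins, queries, Inf)
  expect_true(all(res3$keep))
  expect_error(prescreen_by_similarity(pr$proteins,
                                       Biostrings::AAStringSet(), 1e-6),
               "empty query")
})

test_that("domain filter applies the LRR+kinase criterion exactly", {
  prot <- Biostrings::AAStringSet(c(
    a = paste(rep("M", 300), collapse = ""),
    b = paste(rep("K", 300), collapse = ""),
    c = paste(rep("L", 300), collapse = "")))
  ann <- data.frame(
    gene_id = c(rep("a", 13), "b", rep("c", 2)),
    domain_type = c(rep("LRR", 12), "kinase", "LRR", "LRR", "kinase"),
    start = 1L, end = 24L, score = 1)
  roster <- filter_by_domains(prot, ann)
  expect_setequal(roster$gene_id, c("a", "c"))
  expect_equal(roster$n_LRR[roster$gene_id == "a"], 12)
  expect_equal(roster$n_kinase[roster$gene_id == "a"], 1)
  # "b" has LRR only -> excluded
  expect_false("b" %in% roster$gene_id)

  # membership is monotone under added annotation rows
  more <- rbind(ann, data.frame(gene_id = "b", domain_type = "kinase",
                                start = 30L, end = 60L, score = 1))
  roster2 <- filter_by_domains(prot, more)
  expect_true(all(roster$gene_id %in% roster2$gene_id))
  expect_true("b" %in% roster2$gene_id)

  # out-of-range coordinates are rejected with the offending row
  bad <- rbind(ann, data.frame(gene_id = "a", domain_type = "LRR",
                               start = 290L, end = 350L, score = 1))
  expect_error(filter_by_domains(prot, bad), "exceed")
})

test_that("domain filter recovers generator truth with no error", {
  cfg <- sim_config(seed = 12, n_family = 25, n_decoy = 12)
  pr <- generate_proteome(cfg)
  roster <- filter_by_domains(pr$proteins, pr$annotations)
  expect_setequal(roster$gene_id, pr$truth$gene_id[pr$truth$is_family])
})

test_that("LRR profile scan finds planted repeats and nothing else", {
  pwm <- lrr_pwm()
  consensus_best <- vapply(seq_len(ncol(pwm)), function(j)
    rownames(pwm)[which.max(pwm[, j])][1], character(1))
  # degenerate columns are uniform; use any residue there
  unit <- paste(consensus_best, collapse = "")
  spacer <- paste(rep("G", 10), collapse = "")
  seq3 <- paste0(spacer, unit, spacer, unit, spacer, unit, spacer)
  hits <- scan_lrr_motif(seq3)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$start, c(11, 45, 79))

  # poly-alanine scores below any positive threshold: its window score is
  # strictly negative by direct computation
  polya <- paste(rep("A", 200), collapse = "")
  sm <- log2(pwm * 20)
  polya_score <- sum(sm["A", ])
  expect_lt(polya_score, 0)
  expect_equal(nrow(scan_lrr_motif(polya, threshold = 1e-9)), 0)

  # threshold above the maximum attainable score finds nothing
  max_score <- sum(apply(sm, 2, max))
  expect_equal(nrow(scan_lrr_motif(seq3, threshold = max_score + 1)), 0)
})

test_that("family summary reports subgroup percentages and intron histogram", {
  roster <- data.frame(
    gene_id = sprintf("g%02d", 1:25),
    length = rep(500L, 25),
    n_LRR = 3L, n_kinase = 1L, n_TM = 1L,
    has_signal_peptide = c(rep(TRUE, 14), rep(FALSE, 3), rep(TRUE, 8)),
    subgroup = c(rep("I-a", 17), rep("II", 8)))
  gm <- gene_models(
    genes = data.frame(gene_id = roster$gene_id[1:24], chromosome = "Chr01",
                       start = seq(1, by = 1e6, length.out = 24),
                       end = seq(1, by = 1e6, length.out = 24) + 1000,
                       strand = "+",
                       n_exons = c(1L, rep(2L, 23))),
    exons = data.frame(gene_id = "g01", exon = 1L, start = 1L, end = 1001L))
  expect_warning(s <- summarize_family(roster, gm), "missing a gene model")
  ia <- s$subgroups[s$subgroups$subgroup == "I-a", ]
  expect_equal(ia$n, 17)
  expect_equal(ia$pct_signal_peptide, 82.4)  # 14 of 17
  ii <- s$subgroups[s$subgroups$subgroup == "II", ]
  expect_equal(ii$pct_signal_peptide, 100.0)
  expect_equal(unname(s$intron_histogram["0"]), 1)  # single-exon gene
  expect_equal(unname(s$intron_histogram["1"]), 23)
  expect_equal(s$n_unplaced, 1)
})
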