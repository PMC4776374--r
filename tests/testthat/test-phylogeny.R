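test_that("alignment distances follow their closed forms and gap rules", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  dm <- kinase_distance_matrix(c(x = a, y = b))
  expect_equal(dm["x", "y"], 0.03)
  expect_equal(dm["x", "x"], 0)
  dmp <- kinase_distance_matrix(c(x = a, y = b), model = "poisson")
  expect_equal(dmp["x", "y"], -log(0.97))

  # gapped columns are excluded pairwise
  g1 <- "AC-TT"
  g2 <- "ACG-T"
  dg <- kinase_distance_matrix(c(p = g1, q = g2))
  expect_equal(dg["p", "q"], 0)  # only columns 1,2,5 comparable, all equal
  expect_error(kinase_distance_matrix(c(p = "--AAA", q = "GG---")),
               "no comparable columns")
  expect_error(kinase_distance_matrix(c(x = a)), "at least 2")
})

test_that("neighbor joining recovers a hand-built additive four-taxon tree", {
  # unrooted AB|CD with leaf edges A:1 B:2 C:3 D:4 and internal edge 1
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(nrow(tr$edge), 5)  # 2n-3
  # split AB|CD present
  splits <- famevol:::tree_bipartitions(tr)
  sides <- strsplit(splits$key, "\r", fixed = TRUE)
  expect_true(any(vapply(sides, function(s)
    setequal(s, c("C", "D")) || setequal(s, c("A", "B")), logical(1))))
  # additive distances are reproduced exactly, so all five edge lengths match
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  expect_setequal(round(tr$edge.length, 9), c(1, 2, 3, 4, 1))

  # 3-taxon star solves the three linear equations
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), c(1, 1, 2))

  # n = 2: one edge of total length d
  D2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 5)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)),
               "non-symmetric")
})

test_that("neighbor joining is invariant to input label order", {
  withr::local_seed(21)
  tr <- random_additive_tree(7)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::cophenetic.phylo(t2)[rownames(D), colnames(D)],
               ape::cophenetic.phylo(t1)[rownames(D), colnames(D)],
               tolerance = 1e-9)
})

test_that("neighbor joining agrees with the reference implementation", {
  withr::local_seed(31)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    tr <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(tr)
    mine <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(ref))), 0)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)],
                 ape::cophenetic.phylo(ref)[rownames(D), colnames(D)],
                 tolerance = 1e-9)
  }
})

test_that("bootstrap supports behave at the extremes and are reproducible", {
  # two clearly separated clades: within-clade distance ~0, between ~0.5
  m <- rbind(A = rep(c("A", "C"), 30),
             B = rep(c("A", "C"), 30),
             C = rep(c("G", "T"), 30),
             D = rep(c("G", "T"), 30))
  m[1, 1] <- "C"; m[3, 2] <- "T"  # break exact ties
  bs <- bootstrap_support(m, n_reps = 50, seed = 4)
  expect_equal(bs$support$support, 100)

  one <- bootstrap_support(m, n_reps = 1, seed = 5)
  expect_true(all(one$support$support %in% c(0, 100)))

  again <- bootstrap_support(m, n_reps = 50, seed = 4)
  expect_identical(bs$support, again$support)
  expect_true(all(bs$support$support >= 0 & bs$support$support <= 100))
})

test_that("group labels transfer to nearest reference with deterministic ties", {
  # star-ish tree built from distances: Q near ref1 (0.01), far from ref2
  D <- matrix(c(0, 0.01, 0.8, 0.8,
                0.01, 0, 0.8, 0.8,
                0.8, 0.8, 0, 0.05,
                0.8, 0.8, 0.05, 0), 4, 4,
              dimnames = list(c("Q", "ref1", "ref2", "ref3"),
                              c("Q", "ref1", "ref2", "ref3")))
  tr <- neighbor_joining(D)
  ag <- assign_groups(tr, c(ref1 = "XII-b", ref2 = "I-a", ref3 = "I-b"))
  expect_equal(ag$assignments$group[ag$assignments$gene_id == "Q"], "XII-b")

  # exact tie: equidistant references resolve to the smallest label
  De <- matrix(0.4, 3, 3,
               dimnames = list(c("Q", "refA", "refB"),
                               c("Q", "refA", "refB")))
  diag(De) <- 0
  te <- neighbor_joining(De)
  age <- assign_groups(te, c(refB = "I-b", refA = "I-a"))
  expect_equal(age$assignments$group, "I-a")
  expect_error(assign_groups(te, c(absent = "Z")), "no reference leaves")

  # planted groups from the generator are recovered exactly
  cfg <- sim_config(seed = 13, n_family = 24, n_decoy = 0)
  pr <- generate_proteome(cfg)
  fam <- pr$truth[pr$truth$is_family, ]
  kin <- vapply(seq_len(nrow(fam)), function(i)
    substr(as.character(pr$proteins[[fam$gene_id[i]]]),
           fam$kinase_start[i], fam$kinase_end[i]), character(1))
  names(kin) <- fam$gene_id
  rk <- pr$ref_kinase
  ref_kin <- vapply(seq_len(nrow(rk)), function(i)
    substr(as.character(pr$reference[[rk$gene_id[i]]]),
           rk$kinase_start[i], rk$kinase_end[i]), character(1))
  names(ref_kin) <- rk$gene_id
  tree <- neighbor_joining(kinase_distance_matrix(c(kin, ref_kin)))
  ag2 <- assign_groups(tree, pr$ref_groups)
  got <- ag2$assignments
  truth_grp <- fam$group[match(got$gene_id, fam$gene_id)]
  expect_equal(got$group, truth_grp)
})
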