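# Phylogeny module: p-distance / Poisson distances on aligned kinase
# domains, Saitou-Nei neighbor joining (implemented here, with an explicit
# deterministic tie-break), bootstrap support over alignment columns, and
# nearest-reference group assignment with monophyly diagnostics.

aln_char_matrix <- function(aligned) {
  if (methods::is(aligned, "AAStringSet") ||
      methods::is(aligned, "DNAStringSet")) {
    if (length(unique(Biostrings::width(aligned))) > 1)
      stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(as.character(aligned), ""))
    rownames(m) <- names(aligned)
  } else if (is.matrix(aligned)) {
    m <- aligned
  } else {
    if (length(unique(nchar(aligned))) > 1)
      stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(as.character(aligned), ""))
    if (!is.null(names(aligned))) rownames(m) <- names(aligned)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

#' Pairwise distances on an aligned sequence set
#'
#' Columns where either row carries a gap (`-` or `.`) are ignored for that
#' pair; `p` is the mismatch proportion over compared columns. The Poisson
#' correction is `-ln(1 - p)`.
#'
#' @param aligned `AAStringSet`, character vector or character matrix of
#'   equal-length aligned rows (>= 2).
#' @param model `"p-distance"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal, labelled by row
#'   names.
#' @export
kinase_distance_matrix <- function(aligned,
                                   model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  m <- aln_char_matrix(aligned)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  notgap <- (m != "-" & m != ".") * 1
  comparable <- notgap %*% t(notgap)
  residues <- setdiff(unique(as.vector(m)), c("-", "."))
  matches <- matrix(0, nrow(m), nrow(m))
  for (a in residues) {
    ia <- (m == a) * 1
    matches <- matches + ia %*% t(ia)
  }
  off <- upper.tri(comparable)
  if (any(comparable[off] == 0)) {
    idx <- which(comparable == 0 & off, arr.ind = TRUE)[1, ]
    stop("no comparable columns between ", rownames(m)[idx[1]], " and ",
         rownames(m)[idx[2]])
  }
  p <- 1 - matches / comparable
  diag(p) <- 0
  p[p < 0] <- 0  # numerical noise
  if (model == "poisson") {
    sat <- (1 - p) <= 1e-9 & row(p) != col(p)
    if (any(sat)) {
      idx <- which(sat, arr.ind = TRUE)[1, ]
      stop("saturated distance between ", rownames(m)[idx[1]], " and ",
           rownames(m)[idx[2]], ": Poisson correction undefined")
    }
    p <- -log(1 - p)
  }
  dimnames(p) <- list(rownames(m), rownames(m))
  p
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` joins (ties resolved by the
#' lexicographically smallest pair of cluster labels, a cluster being
#' labelled by its smallest member), branch lengths by the usual
#' half-plus-rate-difference formula, and the final three clusters are
#' joined at the unrooted central node. Negative branch lengths are retained
#' (see [clamp_branch_lengths()]).
#'
#' @param dm symmetric numeric matrix (or `dist`) with zero diagonal.
#' @return an unrooted `phylo` object (2n-3 edges for n >= 3 leaves; for
#'   n = 2 the single edge of length d is returned as two half-edges).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8) stop("non-symmetric distance matrix")
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (n == 2) {
    tr <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
               edge.length = rep(dm[1, 2] / 2, 2),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  D <- unname(dm)
  act <- seq_len(n)              # phylo node ids of active clusters
  reps <- labels                 # smallest member label per cluster
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  nxt <- n + 1L
  while (length(act) > 3) {
    r <- length(act)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    mn <- min(Q)
    cand <- which(Q <= mn + 1e-12 * max(1, abs(mn)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      a <- pmin(reps[cand[, 1]], reps[cand[, 2]])
      b <- pmax(reps[cand[, 1]], reps[cand[, 2]])
      cand <- cand[order(a, b), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    u <- nxt; nxt <- nxt + 1L
    parent <- c(parent, u, u)
    child <- c(child, act[i], act[j])
    elen <- c(elen, bi, bj)
    keep <- setdiff(seq_len(r), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    act <- c(act[keep], u)
    reps <- c(reps[keep], min(reps[i], reps[j]))
  }
  v <- nxt
  if (length(act) == 3) {
    x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    parent <- c(parent, v, v, v)
    child <- c(child, act)
    elen <- c(elen, x1, x2, x3)
  }
  # renumber internals in preorder from the central node (ape convention:
  # root = n+1, cladewise edge order)
  kids <- split(seq_along(parent), parent)   # edge indices by parent
  new_id <- integer(2L * n)
  counter <- n + 1L
  edge_out <- matrix(0L, length(parent), 2)
  len_out <- numeric(length(parent))
  k <- 0L
  stack <- list(list(node = v, parent_new = NA_integer_, len = NA_real_))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    if (node <= n) nid <- node
    else { nid <- counter; counter <- counter + 1L }
    if (!is.na(fr$parent_new)) {
      k <- k + 1L
      edge_out[k, ] <- c(fr$parent_new, nid)
      len_out[k] <- fr$len
    }
    ek <- kids[[as.character(node)]]
    if (!is.null(ek)) {
      for (e in rev(ek)) {
        stack[[length(stack) + 1]] <- list(node = child[e],
                                           parent_new = nid, len = elen[e])
      }
    }
  }
  tr <- list(edge = edge_out, edge.length = len_out,
             tip.label = labels, Nnode = n - 2L)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Clamp negative branch lengths to zero
#'
#' NJ can emit slightly negative branch lengths; this returns a copy with
#' negatives set to 0 and an attribute `n_clamped` counting them.
#' @param tree a `phylo`.
#' @return the clamped `phylo`.
#' @export
clamp_branch_lengths <- function(tree) {
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

# non-trivial bipartitions of an unrooted tree as canonical keys: for each
# internal edge, the tip set on the child side, complemented if it contains
# the reference tip (lexicographically smallest label) so each split has one
# key
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  all_tips <- tree$tip.label
  # tips below each node, postorder
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c_]])
  }
  keys <- character(0)
  nodes <- integer(0)
  root <- n + 1L
  for (e in seq_len(nrow(tree$edge))) {
    c_ <- tree$edge[e, 2]
    if (c_ <= n) next               # leaf edge: trivial split
    side <- below[[c_]]
    if (length(side) >= n - 1) next # trivial
    if (ref %in% side) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, c_)
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree per replicate and counts each internal bipartition of the
#' full-data tree among the replicates. Supports (0-100) are attached as
#' internal node labels of the full-data tree.
#'
#' @param aligned alignment as in [kinase_distance_matrix()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @param model distance model, as in [kinase_distance_matrix()].
#' @return list with `tree` (full-data `phylo`, node labels = supports) and
#'   `support` (data frame: node, support).
#' @export
bootstrap_support <- function(aligned, n_reps = 1000L, seed = 1L,
                              model = "p-distance") {
  stopifnot(n_reps >= 1)
  m <- aln_char_matrix(aligned)
  full <- neighbor_joining(kinase_distance_matrix(m, model))
  bp <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0L, nrow(bp)), bp$key)
  with_rng(seed, {
    L <- ncol(m)
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      tr <- neighbor_joining(kinase_distance_matrix(m[, cols, drop = FALSE],
                                                    model))
      rep_keys <- tree_bipartitions(tr)$key
      hit <- bp$key %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- data.frame(node = bp$node,
                        support = 100 * unname(counts) / n_reps)
  n <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  labs[support$node - n] <- as.character(support$support)
  full$node.label <- labs
  list(tree = full, support = support)
}

#' Transfer group labels from reference leaves by patristic proximity
#'
#' Every unlabeled leaf receives the group of its nearest reference leaf
#' (path-length distance over the tree; ties broken by the lexicographically
#' smallest reference label). A monophyly report states, per group, whether
#' the group's leaves form one clade (i.e. one side of a bipartition).
#'
#' @param tree a `phylo`.
#' @param reference_labels data frame (gene_id, group) or named character
#'   vector mapping reference leaf names to group labels.
#' @return list with `assignments` (gene_id, group, nearest_ref, distance)
#'   and `monophyly` (group, n, monophyletic).
#' @export
assign_groups <- function(tree, reference_labels) {
  if (is.data.frame(reference_labels)) {
    ref <- stats::setNames(reference_labels$group, reference_labels$gene_id)
  } else ref <- reference_labels
  refs <- intersect(names(ref), tree$tip.label)
  if (!length(refs)) stop("no reference leaves present in tree")
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  queries <- setdiff(tree$tip.label, refs)
  rows <- lapply(queries, function(q) {
    d <- D[q, refs]
    dmin <- min(d)
    best <- sort(refs[d <= dmin + 1e-12])[1]
    data.frame(gene_id = q, group = unname(ref[best]), nearest_ref = best,
               distance = dmin, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  grp_of <- c(stats::setNames(assignments$group, assignments$gene_id),
              stats::setNames(unname(ref[refs]), refs))
  keys <- tree_bipartitions(tree)$key
  sides <- strsplit(keys, "\r", fixed = TRUE)
  all_tips <- tree$tip.label
  mono <- lapply(sort(unique(grp_of)), function(g) {
    members <- sort(names(grp_of)[grp_of == g])
    is_clade <- length(members) <= 1 || length(members) >= n - 1 ||
      any(vapply(sides, function(s)
        identical(sort(s), members) ||
          identical(sort(setdiff(all_tips, s)), members), logical(1)))
    data.frame(group = g, n = length(members), monophyletic = is_clade,
               stringsAsFactors = FALSE)
  })
  list(assignments = assignments, monophyly = do.call(rbind, mono))
}
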