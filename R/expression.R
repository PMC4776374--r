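# Expression profiling: gene-wise z-normalization, average-linkage
# hierarchical clustering on 1 - Pearson r, tissue-preference calls,
# duplicate-pair expression divergence, and qPCR 2^(-ddCt).

#' Gene-wise z-score normalization
#'
#' Each row is transformed to `(x - mean) / sd` with the population
#' (divide-by-n) standard deviation; constant rows map to all zeros.
#'
#' @param m nonnegative genes x tissues matrix.
#' @return matrix of the same shape; non-constant rows have mean 0 and
#'   population variance 1.
#' @export
genewise_normalize <- function(m) {
  if (ncol(m) < 1) stop("need at least one tissue")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  out <- (m - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  out[sd_pop == 0, ] <- 0
  out
}

# Pearson-correlation distance between rows; constant rows sit at distance 1
# from everything (keeps the clustering total and deterministic)
pearson_distance <- function(m) {
  sd_pop <- sqrt(rowMeans((m - rowMeans(m))^2))
  const <- sd_pop == 0
  r <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - r
  d[const, ] <- 1
  d[, const] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Distance between genes is `1 - Pearson r` of their expression rows;
#' agglomeration follows the UPGMA merge rule (cluster-size-weighted average
#' of distances), joining the closest pair at each step with ties resolved
#' by the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest member).
#'
#' @param m normalized genes x tissues matrix (>= 2 genes).
#' @return an object of class `hclust` (merge, height, order, labels), so
#'   the full merge history is available and standard plotting works.
#' @export
hierarchical_cluster <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need at least 2 genes")
  labels <- rownames(m) %||% paste0("g", seq_len(n))
  D <- pearson_distance(m)
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negatives are singletons
  reps <- labels
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  diag(D) <- Inf
  D[!active, ] <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub <= mn + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      a <- pmin(reps[idx[cand[, 1]]], reps[idx[cand[, 2]]])
      b <- pmax(reps[idx[cand[, 1]]], reps[idx[cand[, 2]]])
      cand <- cand[order(a, b), , drop = FALSE]
    }
    i <- idx[cand[1, 1]]; j <- idx[cand[1, 2]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- D[i, j]
    # UPGMA update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      dn <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- dn; D[others, i] <- dn
    }
    size[i] <- size[i] + size[j]
    reps[i] <- min(reps[i], reps[j])
    id[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  # leaf order by dendrogram traversal
  order_of <- function(k) {
    if (k < 0) return(-k)
    c(order_of(merge[k, 1]), order_of(merge[k, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1L), labels = labels,
                 method = "average",
                 dist.method = "1 - Pearson r",
                 call = match.call()),
            class = "hclust")
}

#' Tissue-preferential accumulation calls
#'
#' A gene is called preferential in tissue `t` when its value there is at
#' least `fold` times the gene's median over all tissues and at least
#' `floor`. A gene may be called in several tissues.
#'
#' @param m raw (unnormalized) nonnegative expression matrix.
#' @param fold fold-over-median threshold (> 1), default 2.
#' @param floor minimum absolute value, default 1.
#' @return list with `calls` (named list gene -> tissue character vector)
#'   and `counts` (per-tissue gene counts with percentages of all genes).
#' @export
tissue_preference <- function(m, fold = 2, floor = 1) {
  if (fold <= 1) stop("fold must exceed 1")
  med <- apply(m, 1, stats::median)
  hit <- m >= pmax(fold * med, floor)
  # fold * 0 == 0 would call every tissue of an all-zero row; require > 0
  hit[m <= 0] <- FALSE
  calls <- lapply(seq_len(nrow(m)), function(i) colnames(m)[hit[i, ]])
  names(calls) <- rownames(m)
  n_per_tissue <- colSums(hit)
  counts <- data.frame(tissue = colnames(m),
                       n = as.integer(n_per_tissue),
                       pct = percentage(as.integer(n_per_tissue), nrow(m)),
                       stringsAsFactors = FALSE)
  list(calls = calls, counts = counts)
}

#' Expression divergence of duplicate pairs
#'
#' A pair is `similar` when the Pearson correlation of the two expression
#' rows is at least `r_threshold`, otherwise `divergent`. A cluster of genes
#' is similar only if all its member pairs are similar.
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param m expression matrix.
#' @param r_threshold correlation threshold, default 0.8.
#' @param clusters optional cluster membership data frame (cluster_id,
#'   gene_id) for cluster-level calls.
#' @return list with `pairs` (pair table plus r and call; unevaluated pairs
#'   carry call "unevaluated"), `n_similar`, `n_divergent`, `n_unevaluated`,
#'   and optionally `clusters` (cluster_id, n, call).
#' @export
duplicate_expression_divergence <- function(pairs, m, r_threshold = 0.8,
                                            clusters = NULL) {
  r <- rep(NA_real_, nrow(pairs))
  call <- rep("unevaluated", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(m)) || !(gb %in% rownames(m))) {
      warning("pair (", ga, ", ", gb, ") missing from matrix; skipped")
      next
    }
    r[i] <- suppressWarnings(stats::cor(m[ga, ], m[gb, ]))
    call[i] <- if (!is.na(r[i]) && r[i] >= r_threshold) "similar"
               else "divergent"
  }
  pairs$r <- r
  pairs$call <- call
  out <- list(pairs = pairs,
              n_similar = sum(call == "similar"),
              n_divergent = sum(call == "divergent"),
              n_unevaluated = sum(call == "unevaluated"))
  if (!is.null(clusters)) {
    cl <- lapply(split(clusters$gene_id, clusters$cluster_id), function(gs) {
      gs <- intersect(gs, rownames(m))
      if (length(gs) < 2) return(NA)
      combs <- utils::combn(sort(gs), 2)
      all(apply(combs, 2, function(p)
        suppressWarnings(stats::cor(m[p[1], ], m[p[2], ])) >= r_threshold))
    })
    out$clusters <- data.frame(
      cluster_id = names(cl),
      call = vapply(cl, function(x)
        if (is.na(x)) "unevaluated" else if (x) "similar" else "divergent",
        character(1)),
      stringsAsFactors = FALSE)
    rownames(out$clusters) <- NULL
  }
  out
}

#' Relative qPCR expression by the 2^(-ddCt) method
#'
#' `dCt = Ct_target - Ct_reference` for the sample and for the calibrator;
#' the relative level is `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param ct_target,ct_reference sample cycle numbers.
#' @param ct_target_cal,ct_reference_cal calibrator cycle numbers.
#' @return relative expression (vectorized).
#' @export
ddct <- function(ct_target, ct_reference, ct_target_cal, ct_reference_cal) {
  stopifnot(all(is.finite(c(ct_target, ct_reference,
                            ct_target_cal, ct_reference_cal))))
  ddc <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddc)
}
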