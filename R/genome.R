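# Genome organization: chromosome distribution ratios, tandem-duplication
# clusters by single-linkage chaining of start coordinates, and
# tandem/segmental classification of paralog pairs.

#' Per-chromosome counts and distribution ratios
#'
#' Unplaced genes (chromosome `"unplaced"` or any scaffold) are reported
#' separately and excluded from the percentage denominator.
#'
#' @param genes gene table with columns `gene_id` and `chromosome` (a
#'   `gene_models` object is also accepted).
#' @return list with `distribution` (chromosome, n, pct), `n_placed` and
#'   `n_unplaced`.
#' @export
chromosome_distribution <- function(genes) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  unplaced <- grepl("^(unplaced|scaffold)", genes$chromosome,
                    ignore.case = TRUE)
  placed <- genes[!unplaced, , drop = FALSE]
  n_placed <- nrow(placed)
  if (n_placed == 0) {
    return(list(distribution = data.frame(chromosome = character(),
                                          n = integer(), pct = numeric()),
                n_placed = 0L, n_unplaced = sum(unplaced)))
  }
  tab <- table(placed$chromosome)
  dist <- data.frame(chromosome = names(tab),
                     n = as.integer(tab),
                     pct = percentage(as.integer(tab), n_placed),
                     stringsAsFactors = FALSE)
  dist <- dist[order(dist$chromosome), ]
  rownames(dist) <- NULL
  list(distribution = dist, n_placed = n_placed,
       n_unplaced = sum(unplaced))
}

#' Tandem duplication clusters by 200-kb chaining
#'
#' Per chromosome, genes are sorted by start; consecutive genes whose
#' start-to-start distance is at most `window` belong to one chain
#' (single-linkage, so a chain's total span may exceed one window). Chains
#' of two or more genes are clusters.
#'
#' @param genes gene table (or `gene_models`) with `gene_id`, `chromosome`,
#'   `start`.
#' @param window chaining window in bp, default 200 kb.
#' @return list with `clusters` (data frame: cluster_id, chromosome,
#'   gene_id, start), `n_clusters` and `n_clustered_genes`.
#' @export
tandem_clusters <- function(genes, window = 200000) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  if (window <= 0) stop("window must be positive")
  unplaced <- grepl("^(unplaced|scaffold)", genes$chromosome,
                    ignore.case = TRUE)
  g <- genes[!unplaced, , drop = FALSE]
  g <- g[order(g$chromosome, g$start, g$gene_id), ]
  out <- list()
  cid <- 0L
  for (ch in unique(g$chromosome)) {
    gg <- g[g$chromosome == ch, ]
    if (nrow(gg) == 0) next
    chain_id <- cumsum(c(1, diff(gg$start) > window))
    for (k in unique(chain_id)) {
      members <- gg[chain_id == k, ]
      if (nrow(members) < 2) next
      cid <- cid + 1L
      out[[cid]] <- data.frame(cluster_id = sprintf("C%03d", cid),
                               chromosome = ch,
                               gene_id = members$gene_id,
                               start = members$start,
                               stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(), chromosome = character(),
               gene_id = character(), start = numeric())
  rownames(clusters) <- NULL
  list(clusters = clusters,
       n_clusters = length(unique(clusters$cluster_id)),
       n_clustered_genes = nrow(clusters))
}

#' Classify paralog pairs as tandem or segmental
#'
#' A pair is `tandem` when both genes share a tandem cluster. Otherwise it
#' is `segmental` when an evidence flag (mirroring an external collinearity
#' database) marks it, and `segmental-candidate` under the no-evidence
#' fallback.
#'
#' @param pairs data frame with `gene_a`, `gene_b` and optional logical
#'   `evidence`.
#' @param genes gene table (or `gene_models`).
#' @param clusters result of [tandem_clusters()] (or its `clusters` data
#'   frame).
#' @return the pair data frame with a `mode` column plus summary attributes;
#'   `attr(,"pct_segmental_genes")` is the percentage of placed genes
#'   involved in non-tandem pairs.
#' @export
classify_pairs <- function(pairs, genes, clusters) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  if (is.list(clusters) && !is.data.frame(clusters))
    clusters <- clusters$clusters
  if (any(pairs$gene_a == pairs$gene_b))
    stop("pair of a gene with itself: ",
         pairs$gene_a[pairs$gene_a == pairs$gene_b][1])
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), genes$gene_id)
  if (length(missing))
    stop("pair gene absent from gene table: ", missing[1])
  cluster_of <- stats::setNames(clusters$cluster_id, clusters$gene_id)
  ev <- pairs$evidence %||% rep(FALSE, nrow(pairs))
  mode <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ca <- cluster_of[pairs$gene_a[i]]
    cb <- cluster_of[pairs$gene_b[i]]
    if (!is.na(ca) && !is.na(cb) && ca == cb) mode[i] <- "tandem"
    else if (isTRUE(ev[i])) mode[i] <- "segmental"
    else mode[i] <- "segmental-candidate"
  }
  pairs$mode <- mode
  seg_genes <- unique(c(pairs$gene_a[mode != "tandem"],
                        pairs$gene_b[mode != "tandem"]))
  placed <- genes$gene_id[!grepl("^(unplaced|scaffold)", genes$chromosome,
                                 ignore.case = TRUE)]
  k <- length(intersect(seg_genes, placed))
  attr(pairs, "n_segmental_genes") <- k
  attr(pairs, "pct_segmental_genes") <-
    if (length(placed)) percentage(k, length(placed)) else NA_real_
  pairs
}
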