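# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration or direct counting, never by calling the
# implementation code paths they check.

# --- Nei-Gojobori pathway enumeration ---------------------------------------
# Recursive enumeration over sequences of single-site edits turning codon c1
# into c2; scores each full pathway, excludes pathways visiting an
# intermediate stop, averages the rest (all, if every pathway is blocked).
oracle_ng_pair <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (!length(diffs)) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(sd = sd, nd = nd,
                                       blocked = as.numeric(blocked))
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      blk <- blocked || (aa_nxt == "*" && length(remaining) > 1)
      walk(nxt, setdiff(remaining, pos),
           sd + (aa_cur == aa_nxt), nd + (aa_cur != aa_nxt), blk)
    }
  }
  walk(a, diffs, 0, 0, FALSE)
  pm <- do.call(rbind, paths)
  use <- pm[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[use, "sd"]), nd = mean(pm[use, "nd"]))
}

# NG synonymous-site fraction of one codon straight from the code table
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  cv <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (bb in setdiff(c("A", "C", "G", "T"), cv[pos])) {
    alt <- cv; alt[pos] <- bb
    if (code[[paste(alt, collapse = "")]] == aa) s <- s + 1 / 3
  }
  s
}

# --- tandem clustering by explicit transitive closure -----------------------
oracle_tandem <- function(genes, window) {
  out <- list()
  for (ch in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == ch, ]
    n <- nrow(g)
    comp <- seq_len(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (abs(g$start[i] - g$start[j]) <= window) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
    for (k in unique(comp)) {
      members <- g$gene_id[comp == k]
      if (length(members) >= 2)
        out[[length(out) + 1]] <- sort(members)
    }
  }
  out[order(vapply(out, `[`, character(1), 1))]
}

# --- SNP effect by whole-CDS translation ------------------------------------
oracle_effect_coding <- function(cds_seq, cds_pos, alt_base) {
  mut <- cds_seq
  substr(mut, cds_pos, cds_pos) <- alt_base
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                           no.init.codon = TRUE))
  p2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                           no.init.codon = TRUE))
  if (p1 == p2) "synonymous" else "nonsynonymous"
}

# --- misc -------------------------------------------------------------------
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_family = 18, n_decoy = 9,
             n_chromosomes = 5, chromosome_length = 3e7,
             tandem_cluster_spec = data.frame(chromosome = 2L, n = 3L,
                                              spacing = 150000),
             duplicate_pair_spec = data.frame(sd = c(3L, 0L, 10L),
                                              nd = c(0L, 0L, 5L),
                                              L = c(100L, 50L, 200L)),
             pop_spec = data.frame(p_wild = c(0, 1, 0.5),
                                   p_cult = c(0, 0, 0.5),
                                   n_wild = 10L, n_cult = 10L),
             ...)
}
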