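# Family identification: similarity prescreen, the decisive LRR+kinase
# domain criterion, a position-weight-matrix fallback scanner for LRR
# repeats, and per-subgroup structural summaries.

#' Canonical 24-residue plant LRR consensus
#'
#' Conserved positions are literal residues; `X` marks degenerate positions.
#' @return a single character string of length 24.
#' @export
lrr_consensus <- function() "LXXLXXLXLXXNXLSGXIPXXLGX"

#' Position-weight matrix for the plant LRR repeat
#'
#' 20 x 24 probability matrix: conserved consensus positions put weight
#' `conserved_p` on the consensus residue (remainder spread uniformly);
#' degenerate positions are uniform. Scores are log2 odds against a uniform
#' background.
#'
#' @param conserved_p probability mass on the consensus residue at conserved
#'   columns.
#' @return numeric matrix, rows named by amino acid.
#' @export
lrr_pwm <- function(conserved_p = 0.6) {
  cons <- strsplit(lrr_consensus(), "")[[1]]
  m <- matrix(1 / 20, nrow = 20, ncol = length(cons),
              dimnames = list(AA20, NULL))
  for (j in seq_along(cons)) {
    if (cons[j] == "X") next
    m[, j] <- (1 - conserved_p) / 19
    m[cons[j], j] <- conserved_p
  }
  m
}

pwm_score_matrix <- function(pwm) log2(pwm * 20)

#' Scan a protein for LRR repeats with a fixed-length profile
#'
#' Slides the 24-column LRR position-weight matrix along the sequence.
#' Windows scoring at least `threshold` are selected greedily without
#' overlap, by descending score (ties resolved leftmost), and returned
#' sorted by start.
#'
#' @param protein a single protein sequence (character or `AAString`).
#' @param threshold minimum window score; the default is 60% of the maximum
#'   attainable profile score.
#' @param pwm the profile, by default [lrr_pwm()].
#' @return data frame with columns start, end, score (possibly empty).
#' @export
scan_lrr_motif <- function(protein, threshold = NULL, pwm = lrr_pwm()) {
  protein <- as.character(protein)
  if (nchar(protein) == 0) stop("empty protein")
  sm <- pwm_score_matrix(pwm)
  w <- ncol(sm)
  if (is.null(threshold)) threshold <- 0.6 * sum(apply(sm, 2, max))
  n <- nchar(protein)
  empty <- data.frame(start = integer(), end = integer(), score = numeric())
  if (n < w) return(empty)
  chars <- strsplit(protein, "")[[1]]
  idx <- match(chars, rownames(sm))  # NA for nonstandard residues
  scores <- vapply(seq_len(n - w + 1L), function(s) {
    cols <- seq_len(w)
    r <- idx[s + cols - 1L]
    if (anyNA(r)) return(-Inf)
    sum(sm[cbind(r, cols)])
  }, numeric(1))
  cand <- which(scores >= threshold)
  if (!length(cand)) return(empty)
  cand <- cand[order(-scores[cand], cand)]  # descending score, ties leftmost
  taken <- logical(n)
  keep <- integer(0)
  for (s in cand) {
    span <- s:(s + w - 1L)
    if (!any(taken[span])) {
      keep <- c(keep, s)
      taken[span] <- TRUE
    }
  }
  keep <- sort(keep)
  data.frame(start = keep, end = keep + w - 1L, score = scores[keep])
}

#' Similarity prescreen against a reference query set
#'
#' Scores each candidate against every query with Smith-Waterman local
#' alignment (BLOSUM62, gap open 11 / extend 1) and converts the best score
#' to an E-value with the Karlin-Altschul formula `E = K m n exp(-lambda S)`
#' using the published gapped BLOSUM62 parameters (lambda = 0.267,
#' K = 0.041). Candidates whose best E-value is below `evalue_threshold`
#' are retained, in their original order.
#'
#' @param candidates `AAStringSet` (or named character) of candidate
#'   proteins.
#' @param queries `AAStringSet` (or named character) of reference proteins.
#' @param evalue_threshold E-value cutoff, default `1e-6`.
#' @return data frame with columns gene_id, best_score, best_query, evalue,
#'   keep; attribute `kept` holds the retained candidate names.
#' @export
prescreen_by_similarity <- function(candidates, queries,
                                    evalue_threshold = 1e-6) {
  if (evalue_threshold <= 0) stop("evalue_threshold must be positive")
  if (!methods::is(candidates, "AAStringSet"))
    candidates <- Biostrings::AAStringSet(candidates)
  if (!methods::is(queries, "AAStringSet"))
    queries <- Biostrings::AAStringSet(queries)
  if (length(queries) == 0) stop("empty query set")
  if (length(candidates) == 0) stop("empty candidate set")
  lambda <- 0.267
  K <- 0.041
  n_db <- sum(Biostrings::width(queries))
  best_score <- rep(-Inf, length(candidates))
  best_query <- rep(NA_character_, length(candidates))
  for (qi in seq_along(queries)) {
    sc <- Biostrings::pairwiseAlignment(
      candidates, queries[[qi]], type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    hit <- sc > best_score
    best_score[hit] <- sc[hit]
    best_query[hit] <- names(queries)[qi]
  }
  evalue <- K * Biostrings::width(candidates) * n_db *
    exp(-lambda * best_score)
  out <- data.frame(gene_id = names(candidates),
                    best_score = best_score,
                    best_query = best_query,
                    evalue = evalue,
                    keep = evalue < evalue_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "kept") <- out$gene_id[out$keep]
  out
}

#' Apply the family membership criterion to annotated candidates
#'
#' A candidate is a family member when its annotation table contains at
#' least one `LRR` and at least one `kinase` interval. Identical gene ids
#' (or identical protein sequences, when sequences are supplied) collapse to
#' the lexicographically smallest id.
#'
#' @param candidates `AAStringSet` or named character of candidate proteins.
#' @param annotations data frame with columns gene_id, domain_type, start,
#'   end (1-based inclusive protein coordinates) and optionally score.
#' @return data frame roster: gene_id, length, n_LRR, n_kinase, n_TM,
#'   has_signal_peptide. Group/subgroup columns are filled in later by the
#'   phylogeny module.
#' @export
filter_by_domains <- function(candidates, annotations) {
  if (!methods::is(candidates, "AAStringSet"))
    candidates <- Biostrings::AAStringSet(candidates)
  lens <- stats::setNames(Biostrings::width(candidates), names(candidates))
  known <- annotations$gene_id %in% names(candidates)
  if (any(!known))
    stop("annotation row refers to unknown candidate: ",
         annotations$gene_id[!known][1])
  bad <- annotations$start < 1 | annotations$start > annotations$end |
    annotations$end > lens[annotations$gene_id]
  if (any(bad))
    stop("annotation coordinates exceed protein length in row ",
         which(bad)[1], " (", annotations$gene_id[bad][1], ")")
  ok_types <- c("LRR", "kinase", "TM", "signal_peptide")
  if (!all(annotations$domain_type %in% ok_types))
    stop("unknown domain_type: ",
         setdiff(annotations$domain_type, ok_types)[1])

  # redundancy: identical sequence collapses to smallest id
  ids <- sort(names(candidates))
  seqs <- as.character(candidates)[ids]
  keep_ids <- ids[!duplicated(seqs)]

  count_type <- function(id, type)
    sum(annotations$gene_id == id & annotations$domain_type == type)
  rows <- lapply(keep_ids, function(id) {
    n_lrr <- count_type(id, "LRR")
    n_kin <- count_type(id, "kinase")
    if (n_lrr < 1 || n_kin < 1) return(NULL)
    data.frame(gene_id = id,
               length = unname(lens[id]),
               n_LRR = n_lrr,
               n_kinase = n_kin,
               n_TM = count_type(id, "TM"),
               has_signal_peptide = count_type(id, "signal_peptide") > 0,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), length = integer(),
               n_LRR = integer(), n_kinase = integer(), n_TM = integer(),
               has_signal_peptide = logical())
  rownames(out) <- NULL
  out
}

#' Summarize family structure per subgroup
#'
#' Per subgroup: member count, protein length range and the percentage of
#' members with a signal peptide (one decimal, half away from zero);
#' family-wide: a histogram of intron counts (exons - 1 from the gene
#' models). Members without a gene model are tallied in an `unplaced` bin
#' with a warning.
#'
#' @param roster output of [filter_by_domains()], optionally with a
#'   `subgroup` column (members lacking one fall into subgroup
#'   "unassigned").
#' @param gene_models a `gene_models` object.
#' @return list with data frame `subgroups` (subgroup, n, min_length,
#'   max_length, pct_signal_peptide), table `intron_histogram`, and count
#'   `n_unplaced`.
#' @export
summarize_family <- function(roster, gene_models) {
  if (nrow(roster) == 0) stop("empty roster")
  sg <- roster$subgroup %||% rep("unassigned", nrow(roster))
  sg[is.na(sg)] <- "unassigned"
  by_sg <- split(seq_len(nrow(roster)), sg)
  subgroups <- do.call(rbind, lapply(names(by_sg), function(s) {
    i <- by_sg[[s]]
    data.frame(subgroup = s, n = length(i),
               min_length = min(roster$length[i]),
               max_length = max(roster$length[i]),
               pct_signal_peptide =
                 percentage(sum(roster$has_signal_peptide[i]), length(i)),
               stringsAsFactors = FALSE)
  }))
  idx <- match(roster$gene_id, gene_models$genes$gene_id)
  n_unplaced <- sum(is.na(idx))
  if (n_unplaced > 0)
    warning(n_unplaced, " roster member(s) missing a gene model")
  introns <- gene_models$genes$n_exons[idx[!is.na(idx)]] - 1L
  list(subgroups = subgroups,
       intron_histogram = table(introns),
       n_unplaced = n_unplaced)
}
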