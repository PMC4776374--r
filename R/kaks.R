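# Molecular evolution: codon-aware pairwise alignment, Nei-Gojobori (1986)
# Ka/Ks with Jukes-Cantor correction, synonymous-clock dating of duplication
# events, Ks-distribution binning and omega-based divergence categories.

#' Evolutionary-rate parameters
#'
#' @param lambda_rate synonymous clock rate, substitutions per synonymous
#'   site per year (soybean: 6.1e-9).
#' @param omega_cutoff Ka/Ks boundary between purifying-dominated and
#'   diverging pairs.
#' @param ks_bin_width,ks_max Ks histogram layout; the 0.06 width anchored
#'   at 0 makes the bin edges land on 0.12/0.18 and 0.54/0.60.
#' @return list of class `evol_params`.
#' @export
evol_params <- function(lambda_rate = 6.1e-9, omega_cutoff = 0.3,
                        ks_bin_width = 0.06, ks_max = 1.02) {
  stopifnot(lambda_rate > 0, omega_cutoff > 0, ks_bin_width > 0, ks_max > 0)
  structure(list(lambda_rate = lambda_rate, omega_cutoff = omega_cutoff,
                 ks_bin_width = ks_bin_width, ks_max = ks_max),
            class = "evol_params")
}

#' Codon alignment of two CDS
#'
#' Both rows must be equal length, divisible by three, and translate
#' without internal stop codons after removing gaps. Codons containing a
#' gap in either row are excluded from all counting.
#'
#' @param a,b aligned CDS strings (gaps as `-`).
#' @return list of class `codon_alignment`.
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) stop("aligned CDS differ in length")
  if (nchar(a) %% 3 != 0) stop("alignment length not divisible by 3")
  for (s in c(a, b)) {
    ungapped <- gsub("-", "", s)
    if (nchar(ungapped) %% 3 != 0)
      stop("ungapped CDS length not divisible by 3")
    translate_cds(ungapped)  # errors on internal stop
  }
  structure(list(a = a, b = b), class = "codon_alignment")
}

#' Back-translate a protein alignment onto its CDS pair
#'
#' Expands each protein gap into a codon triple-gap so the two CDS become a
#' codon alignment. Each CDS must translate exactly to its ungapped protein
#' row (a trailing stop codon on the CDS is tolerated and stripped).
#'
#' @param protein_aln character vector of two aligned protein rows.
#' @param cds_a,cds_b the CDS of the first and second row.
#' @return a [codon_alignment()].
#' @export
backtranslate_align <- function(protein_aln, cds_a, cds_b) {
  stopifnot(length(protein_aln) == 2)
  expand <- function(prot_row, cds) {
    cds <- toupper(as.character(cds))
    cods <- split_codons(cds)
    if (length(cods) > 1 && translate_codon(cods[length(cods)]) == "*")
      cods <- cods[-length(cods)]
    aa_cds <- translate_codon(cods)
    chars <- strsplit(prot_row, "")[[1]]
    aa_prot <- chars[chars != "-"]
    if (length(aa_prot) != length(cods))
      stop("CDS and protein row differ in length (", length(cods),
           " codons vs ", length(aa_prot), " residues)")
    mism <- which(aa_cds != aa_prot)
    if (length(mism))
      stop("translation mismatch at codon ", mism[1], ": CDS codon ",
           cods[mism[1]], " encodes ", aa_cds[mism[1]], ", protein has ",
           aa_prot[mism[1]])
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    paste(out, collapse = "")
  }
  codon_alignment(expand(protein_aln[1], cds_a),
                  expand(protein_aln[2], cds_b))
}

perms_of <- function(k) {
  switch(k,
         matrix(1L, 1, 1),
         rbind(c(1L, 2L), c(2L, 1L)),
         rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair: enumerate all orderings of the differing positions, score each step
# by amino-acid identity, exclude orderings passing through an intermediate
# stop codon (if every ordering is excluded, average over all of them)
ng_pathway_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(.fe$ngpath)) .fe$ngpath <- new.env(parent = emptyenv())
  cached <- get0(key, envir = .fe$ngpath)
  if (!is.null(cached)) return(cached)
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  k <- length(diffs)
  if (k == 0) return(c(sd = 0, nd = 0))
  code <- genetic_code()
  P <- perms_of(k)
  sd_all <- nd_all <- numeric(nrow(P))
  ok <- logical(nrow(P))
  for (r in seq_len(nrow(P))) {
    cur <- a
    sd <- nd <- 0
    blocked <- FALSE
    for (si in seq_len(k)) {
      pos <- diffs[P[r, si]]
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && si < k) blocked <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    sd_all[r] <- sd; nd_all[r] <- nd; ok[r] <- !blocked
  }
  use <- if (any(ok)) ok else rep(TRUE, nrow(P))
  out <- c(sd = mean(sd_all[use]), nd = mean(nd_all[use]))
  assign(key, out, envir = .fe$ngpath)
  out
}

#' Nei-Gojobori Ka/Ks for a codon alignment
#'
#' Synonymous site counts per codon are the fractions of the nine possible
#' single-nucleotide changes that preserve the amino acid (changes into stop
#' codons count as nonsynonymous, keeping S + N = 3 per codon), averaged
#' between the two sequences. Multi-difference codons are counted by
#' averaging over all minimal substitution pathways, excluding pathways that
#' pass through a stop codon. Proportions are Jukes-Cantor corrected:
#' `Ks = -(3/4) ln(1 - (4/3) pS)` and analogously for Ka.
#'
#' @param ca a [codon_alignment()].
#' @return list of class `ng_result`: n_codons, S, N, Sd, Nd, pS, pN, Ks,
#'   Ka, omega, omega_defined, saturated_s, saturated_n.
#' @export
nei_gojobori <- function(ca) {
  stopifnot(inherits(ca, "codon_alignment"))
  ca_cod <- split_codons(ca$a)
  cb_cod <- split_codons(ca$b)
  keep <- !grepl("-", ca_cod, fixed = TRUE) & !grepl("-", cb_cod, fixed = TRUE)
  ca_cod <- ca_cod[keep]; cb_cod <- cb_cod[keep]
  if (!length(ca_cod)) stop("no comparable codons")
  syn <- codon_syn_sites_table()
  S <- (sum(syn[ca_cod]) + sum(syn[cb_cod])) / 2
  n_codons <- length(ca_cod)
  N <- 3 * n_codons - S
  Sd <- Nd <- 0
  for (i in seq_len(n_codons)) {
    if (ca_cod[i] == cb_cod[i]) next
    cnt <- ng_pathway_counts(ca_cod[i], cb_cod[i])
    Sd <- Sd + cnt[["sd"]]
    Nd <- Nd + cnt[["nd"]]
  }
  pS <- Sd / S
  pN <- Nd / N
  # + 0 normalizes IEEE negative zero when p == 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3) + 0
  Ks <- jc(pS); Ka <- jc(pN)
  omega_defined <- !is.na(Ks) && !is.na(Ka) && Ks > 0
  structure(list(n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka,
                 omega = if (omega_defined) Ka / Ks else NA_real_,
                 omega_defined = omega_defined,
                 saturated_s = pS >= 0.75, saturated_n = pN >= 0.75),
            class = "ng_result")
}

#' @export
print.ng_result <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori: %d codons | S=%.3f N=%.3f | Sd=%.2f Nd=%.2f | Ks=%s Ka=%s omega=%s\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    formatC(x$Ks, digits = 4), formatC(x$Ka, digits = 4),
    if (x$omega_defined) formatC(x$omega, digits = 3) else "undef"))
  invisible(x)
}

#' Date a duplication event from its synonymous distance
#'
#' `T = Ks / (2 lambda)`, reported in million years to one decimal.
#'
#' @param Ks synonymous substitutions per synonymous site (finite, >= 0;
#'   `NA` for saturated pairs returns `NA`).
#' @param params an [evol_params()].
#' @return age in MY (one decimal).
#' @export
date_duplication <- function(Ks, params = evol_params()) {
  out <- rep(NA_real_, length(Ks))
  ok <- !is.na(Ks)
  if (any(Ks[ok] < 0)) stop("Ks must be nonnegative")
  out[ok] <- round_half_away(Ks[ok] / (2 * params$lambda_rate) / 1e6, 1)
  out
}

#' Ks histogram with modal bins
#'
#' Fixed bins `[0, w, 2w, ..., ks_max)`; peaks are bins whose count strictly
#' exceeds both neighbors (boundary bins are compared to their single
#' neighbor); empty bins are never peaks.
#'
#' @param ks numeric vector of Ks values (or a data frame with a `Ks`
#'   column); `NA` (saturated) values are dropped.
#' @param params an [evol_params()].
#' @return list with `histogram` (bin_low, bin_high, count), `peaks`
#'   (subset of histogram rows) and `n_outside`.
#' @export
ks_histogram <- function(ks, params = evol_params()) {
  if (is.data.frame(ks)) ks <- ks$Ks
  ks <- ks[!is.na(ks)]
  breaks <- seq(0, params$ks_max, by = params$ks_bin_width)
  if (abs(breaks[length(breaks)] - params$ks_max) > 1e-12)
    breaks <- c(breaks, params$ks_max)
  inside <- ks >= 0 & ks < params$ks_max
  idx <- findInterval(ks[inside], breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  hist <- data.frame(bin_low = breaks[-length(breaks)],
                     bin_high = breaks[-1],
                     count = counts)
  nb <- nrow(hist)
  is_peak <- logical(nb)
  for (i in seq_len(nb)) {
    if (counts[i] == 0) next
    left_ok <- i == 1 || counts[i] > counts[i - 1]
    right_ok <- i == nb || counts[i] > counts[i + 1]
    is_peak[i] <- left_ok && right_ok
  }
  list(histogram = hist, peaks = hist[is_peak, , drop = FALSE],
       n_outside = sum(!inside))
}

#' Partition paralog pairs by Ka/Ks cutoff
#'
#' @param omega numeric omega values (or a data frame with an `omega`
#'   column); `NA` means omega undefined.
#' @param params an [evol_params()].
#' @return list with counts `n_below` (omega strictly below the cutoff),
#'   `n_at_or_above` and `n_undefined`.
#' @export
categorize_omega <- function(omega, params = evol_params()) {
  if (is.data.frame(omega)) omega <- omega$omega
  list(n_below = sum(!is.na(omega) & omega < params$omega_cutoff),
       n_at_or_above = sum(!is.na(omega) & omega >= params$omega_cutoff),
       n_undefined = sum(is.na(omega)))
}

#' Ka/Ks table for a set of paralog CDS pairs
#'
#' For each pair: translate both CDS, align the proteins globally
#' (BLOSUM62), back-translate onto the CDS, run [nei_gojobori()] and date
#' the duplication.
#'
#' @param cds named `DNAStringSet` (or character) holding every pair member.
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param params an [evol_params()].
#' @return data frame: gene_a, gene_b, n_codons, S, N, Sd, Nd, pS, pN, Ks,
#'   Ka, omega, age_my.
#' @export
compute_kaks_pairs <- function(cds, pairs, params = evol_params()) {
  if (!methods::is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(cds)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    sa <- as.character(cds[[ga]]); sb <- as.character(cds[[gb]])
    strip_stop <- function(s) {
      cods <- split_codons(s)
      if (translate_codon(cods[length(cods)]) == "*")
        paste(cods[-length(cods)], collapse = "") else s
    }
    sa <- strip_stop(sa); sb <- strip_stop(sb)
    pa <- translate_cds(sa); pb <- translate_cds(sb)
    if (identical(pa, pb) || nchar(pa) == nchar(pb)) {
      # equal-length proteins: positional (gapless) alignment
      aln <- c(pa, pb)
    } else {
      al <- Biostrings::pairwiseAlignment(pa, pb, type = "global",
                                          substitutionMatrix = "BLOSUM62",
                                          gapOpening = 11, gapExtension = 1)
      aln <- c(as.character(Biostrings::alignedPattern(al)),
               as.character(Biostrings::alignedSubject(al)))
    }
    ca <- backtranslate_align(aln, sa, sb)
    ng <- nei_gojobori(ca)
    data.frame(gene_a = ga, gene_b = gb, n_codons = ng$n_codons,
               S = ng$S, N = ng$N, Sd = ng$Sd, Nd = ng$Nd,
               pS = ng$pS, pN = ng$pN, Ks = ng$Ks, Ka = ng$Ka,
               omega = ng$omega,
               age_my = date_duplication(ng$Ks, params),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
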