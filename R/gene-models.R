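# Gene model container and GFF3 interchange. A `gene_models` object is a
# plain list of data frames (genes, exons, cds_spans) plus optional CDS
# sequences; coordinates are 1-based inclusive throughout (GFF3 convention).

#' Construct and validate a gene-model table
#'
#' @param genes data frame with columns gene_id, chromosome, start, end,
#'   strand, n_exons.
#' @param exons data frame with columns gene_id, exon, start, end (sorted,
#'   disjoint within a gene).
#' @param cds_spans data frame like `exons`, the coding subset.
#' @param cds_seq optional named character vector of CDS sequences.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds_spans = exons, cds_seq = character()) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end", "strand") %in%
                  names(genes)))
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  for (id in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == id, ]
    ex <- ex[order(ex$start), ]
    if (any(ex$start > ex$end)) stop("exon with start > end in ", id)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in ", id)
  }
  if (length(cds_seq)) {
    bad <- names(cds_seq)[nchar(cds_seq) %% 3 != 0]
    if (length(bad)) stop("CDS length not divisible by 3: ", bad[1])
  }
  structure(list(genes = genes, exons = exons, cds_spans = cds_spans,
                 cds_seq = cds_seq),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chromosome)), "sequences\n")
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene, exon and CDS features with ID/Parent attributes.
#'
#' @param gm a `gene_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gm, path) {
  lines <- "##gff-version 3"
  g <- gm$genes[order(gm$genes$chromosome, gm$genes$start), ]
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    lines <- c(lines, paste(r$chromosome, "famevol", "gene", r$start, r$end,
                            ".", r$strand, ".", paste0("ID=", r$gene_id),
                            sep = "\t"))
    ex <- gm$exons[gm$exons$gene_id == r$gene_id, ]
    ex <- ex[order(ex$start), ]
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines, paste(r$chromosome, "famevol", "exon",
                              ex$start[e], ex$end[e], ".", r$strand, ".",
                              paste0("Parent=", r$gene_id), sep = "\t"))
    }
    cd <- gm$cds_spans[gm$cds_spans$gene_id == r$gene_id, ]
    cd <- cd[order(cd$start), ]
    for (e in seq_len(nrow(cd))) {
      lines <- c(lines, paste(r$chromosome, "famevol", "CDS",
                              cd$start[e], cd$end[e], ".", r$strand, "0",
                              paste0("Parent=", r$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/exon/CDS features (via rtracklayer) back into the
#' `gene_models` structure written by [write_gff3()].
#'
#' @param path GFF3 file.
#' @return a `gene_models` object (without sequences).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  df <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    id = if (!is.null(md$ID)) as.character(md$ID) else NA_character_,
    parent = parent,
    stringsAsFactors = FALSE)
  gdf <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gdf$id, chromosome = gdf$chromosome,
                      start = gdf$start, end = gdf$end, strand = gdf$strand,
                      stringsAsFactors = FALSE)
  edf <- df[df$type == "exon", ]
  exons <- data.frame(gene_id = edf$parent, start = edf$start, end = edf$end,
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), ]
  exons$exon <- stats::ave(exons$start, exons$gene_id, FUN = seq_along)
  cdf <- df[df$type == "CDS", ]
  cds <- data.frame(gene_id = cdf$parent, start = cdf$start, end = cdf$end,
                    stringsAsFactors = FALSE)
  cds <- cds[order(cds$gene_id, cds$start), ]
  genes$n_exons <- as.integer(table(exons$gene_id)[genes$gene_id])
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  gene_models(genes, exons, cds)
}

# --- coordinate mapping between CDS and genome -------------------------------

# genomic position of the cds_pos-th coding base (1-based, transcription
# order); exons must all be coding, sorted by genomic start
genomic_position_of_cds <- function(cds_pos, exons, strand) {
  exons <- exons[order(exons$start), ]
  len <- exons$end - exons$start + 1L
  if (strand == "+") {
    cum <- cumsum(len)
    e <- which(cds_pos <= cum)[1]
    if (is.na(e)) stop("CDS position beyond gene")
    off <- cds_pos - c(0L, cum)[e]
    exons$start[e] + off - 1L
  } else {
    # transcription runs right to left over exons in reverse genomic order
    cum <- cumsum(rev(len))
    e_rev <- which(cds_pos <= cum)[1]
    if (is.na(e_rev)) stop("CDS position beyond gene")
    off <- cds_pos - c(0L, cum)[e_rev]
    e <- nrow(exons) - e_rev + 1L
    exons$end[e] - off + 1L
  }
}

# CDS offset of a genomic position; NA when the position is not coding
cds_position_of_genomic <- function(gpos, exons, strand) {
  exons <- exons[order(exons$start), ]
  len <- exons$end - exons$start + 1L
  hit <- which(gpos >= exons$start & gpos <= exons$end)
  if (!length(hit)) return(NA_integer_)
  e <- hit[1]
  if (strand == "+") {
    sum(len[seq_len(e - 1L)]) + (gpos - exons$start[e] + 1L)
  } else {
    n <- nrow(exons)
    after <- if (e < n) sum(len[(e + 1L):n]) else 0L
    after + (exons$end[e] - gpos + 1L)
  }
}
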