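# Standard genetic code helpers shared by the simulator, the Ka/Ks engine and
# the SNP effect annotator. The code table itself comes from Biostrings.

.fe <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.fe$code)) .fe$code <- Biostrings::GENETIC_CODE
  .fe$code
}

all_codons <- function() {
  if (is.null(.fe$codons)) {
    b <- c("A", "C", "G", "T")
    .fe$codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  }
  .fe$codons
}

stop_codons <- function() names(genetic_code())[genetic_code() == "*"]

sense_codons <- function() names(genetic_code())[genetic_code() != "*"]

translate_codon <- function(codon) unname(genetic_code()[codon])

is_stop <- function(codon) translate_codon(codon) == "*"

# Nei-Gojobori (1986) synonymous site count of one codon: at each of the 3
# positions, the fraction of the 3 possible single-nucleotide changes that
# leave the amino acid unchanged. Changes into stop codons count as
# nonsynonymous so that s + n == 3 exactly for every codon.
codon_syn_sites <- function(codon) {
  tab <- codon_syn_sites_table()
  unname(tab[codon])
}

codon_syn_sites_table <- function() {
  if (!is.null(.fe$syn_sites)) return(.fe$syn_sites)
  code <- genetic_code()
  bases <- c("A", "C", "G", "T")
  out <- vapply(all_codons(), function(cod) {
    aa <- code[[cod]]
    cv <- strsplit(cod, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, cv[pos])) {
        alt <- cv
        alt[pos] <- b
        if (code[[paste(alt, collapse = "")]] == aa) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  .fe$syn_sites <- out
  out
}

# split a CDS string into codon triplets
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# translate a CDS character string; errors on internal stop when check = TRUE
translate_cds <- function(cds, check_internal_stop = TRUE) {
  cods <- split_codons(cds)
  aa <- translate_codon(cods)
  if (check_internal_stop && any(aa[-length(aa)] == "*"))
    stop("internal stop codon at codon ", which(aa[-length(aa)] == "*")[1])
  paste(aa, collapse = "")
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}
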