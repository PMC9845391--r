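# Builders and independent oracles shared across the suite. Oracles are
# deliberately brute-force and do not call the code paths they check.

# toy transcript model from exon lengths (contiguous coding coordinates)
toy_model <- function(lengths, psi = rep(1, length(lengths))) {
  ends <- cumsum(lengths)
  transcript_model(data.frame(exon_number = seq_along(lengths),
                              cds_start = ends - lengths + 1,
                              cds_end = ends,
                              psi = psi))
}

toy_partition <- function(labels, ranges) {
  region_partition(stats::setNames(ranges, labels))
}

# --- translation oracle ------------------------------------------------------
# Standard-code translation, written from the codon table, independent of any
# package arithmetic.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(bases, as.vector(t(outer(bases, bases, paste0))),
                              paste0)))
  stats::setNames(aas, codons)
})

translate_cds <- function(seq) {
  n <- (nchar(seq) %/% 3) * 3
  codons <- substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
  unname(.codon_table[codons])
}

# random CDS of n_codons with no internal stop in the reference frame
random_cds <- function(n_codons) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
               collapse = "")
    aa <- translate_cds(s)
    if (!any(aa == "*")) return(s)
  }
}

# Apply a small indel at 1-based nucleotide position, return mutant sequence
mutate_cds <- function(seq, pos, type = c("del1", "del2", "dup1", "dup2")) {
  type <- match.arg(type)
  pre <- substr(seq, 1, pos - 1)
  if (type == "del1") paste0(pre, substr(seq, pos + 1, nchar(seq)))
  else if (type == "del2") paste0(pre, substr(seq, pos + 2, nchar(seq)))
  else if (type == "dup1") paste0(pre, substr(seq, pos, pos),
                                  substr(seq, pos, nchar(seq)))
  else paste0(pre, substr(seq, pos, pos + 1),
              substr(seq, pos, nchar(seq)))
}

# First stop residue of a mutant CDS, scanning the full translation; NA if
# no stop is reached.
first_stop_residue <- function(mutant) {
  aa <- translate_cds(mutant)
  w <- which(aa == "*")
  if (length(w) == 0L) NA_integer_ else w[1L]
}

# --- exact-test oracles ------------------------------------------------------
# Minimum-likelihood two-sided binomial p by exhaustive enumeration.
binom_oracle <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)])
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration over all
# tables with the observed margins.
fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  ks <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
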