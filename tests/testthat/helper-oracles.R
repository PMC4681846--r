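# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (index arithmetic, joins, matrix
# algebra) so the two routes can disagree.

# dictionary-style canonical k-mer counter over explicit window strings
oracle_kmer_freq <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(setNames(numeric(length(canonical_kmers(k))),
                             canonical_kmers(k)))
  win <- substring(seq, 1:(L - k + 1), k:L)
  win <- win[!grepl("[^ACGT]", win)]
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", win))
  canon <- ifelse(win <= rc, win, rc)
  out <- setNames(numeric(length(canonical_kmers(k))), canonical_kmers(k))
  if (length(canon)) {
    tab <- table(canon)
    out[names(tab)] <- as.numeric(tab) / length(canon)
  }
  out
}

# direct covariance eigendecomposition
oracle_pca <- function(x, m) {
  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  list(values = eg$values[seq_len(m)],
       vectors = eg$vectors[, seq_len(m), drop = FALSE])
}

# hand confusion-matrix metrics (bases)
oracle_metrics <- function(truth, label, w) {
  tp <- sum(w[truth == "clean" & label == "CLEAN"])
  fn <- sum(w[truth == "clean" & label == "CONTAMINANT"])
  tn <- sum(w[truth == "contaminant" & label == "CONTAMINANT"])
  fp <- sum(w[truth == "contaminant" & label == "CLEAN"])
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fn + tn + fp))
}

random_contigs <- function(n, len_range = c(200L, 1500L), seed = 1L,
                           prefix = "r") {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    seq = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1)),
    length = lens
  )
}

rc_string <- function(x) stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))

# a small constructed hit row
mk_hit <- function(query_id, subject_id, lineage, bitscore = 500,
                   identity = 0.99, aln_len = 400) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 identity = identity, aln_len = as.integer(aln_len),
                 mismatches = 0L, gap_opens = 0L, qstart = 1L,
                 qend = as.integer(aln_len), sstart = 1L,
                 send = as.integer(aln_len), evalue = 0,
                 bitscore = bitscore, subject_lineage = lineage)
}

# projection-table builder for cutoff tests: points on the PC1 axis
mk_points <- function(d, w = rep(1000, length(d)), prefix = "p") {
  tibble::tibble(contig_id = sprintf("%s%02d", prefix, seq_along(d)),
                 weight = w, projectable = TRUE, PC1 = d, PC2 = 0, PC3 = 0)
}

lin_target <- "Bacteria;PhylA;ClassA;OrdA;FamA;GenA;speciesA"
lin_other_phy <- "Bacteria;PhylB;ClassB;OrdB;FamB;GenB;speciesB"
lin_euk <- "Eukaryota;Ascomycota;Saccharomycetes;Sacch;Sacch;Sacch;cerevisiae"
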