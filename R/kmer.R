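# Canonical k-mer machinery.
#
# A canonical k-mer is the lexicographic minimum of a word and its reverse
# complement; pooling strands makes composition vectors invariant to the
# (arbitrary) orientation of an assembled contig. With A<C<G<T encoded as
# 0..3 the reverse complement of an index is computable arithmetically, so
# the fold from the 4^k dense count vector to the canonical space is a
# precomputed integer map, cached per k.

.kmer_fold <- function(k) {
  key <- paste0("fold", k)
  if (!is.null(.prodege_cache[[key]])) return(.prodege_cache[[key]])
  n <- 4L^k
  i <- 0:(n - 1)
  rc <- integer(n)
  for (j in seq_len(k) - 1L) {          # digit with weight 4^(k-1-j)
    d <- (i %/% 4L^(k - 1L - j)) %% 4L
    rc <- rc + (3L - d) * 4L^j
  }
  canon <- pmin(i, rc)
  levels <- sort(unique(canon))
  fold <- list(group = match(canon, levels),   # 4^k -> 1..D
               canon_idx = levels,
               dim = length(levels))
  .prodege_cache[[key]] <- fold
  fold
}

.kmer_names <- function(k) {
  key <- paste0("names", k)
  if (!is.null(.prodege_cache[[key]])) return(.prodege_cache[[key]])
  fold <- .kmer_fold(k)
  bases <- c("A", "C", "G", "T")
  idx <- fold$canon_idx
  out <- character(length(idx))
  chars <- matrix("", nrow = length(idx), ncol = k)
  for (j in seq_len(k) - 1L) {
    chars[, j + 1L] <- bases[((idx %/% 4L^(k - 1L - j)) %% 4L) + 1L]
  }
  out <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  .prodege_cache[[key]] <- out
  out
}

#' Canonical k-mers
#'
#' @param k Word size, 1-12.
#' @return Character vector of all canonical k-mers in index order; its
#'   length is `(4^k + s)/2` where `s` counts self-reverse-complement
#'   words (zero for odd `k`).
#' @export
canonical_kmers <- function(k) {
  check_k(k)
  .kmer_names(as.integer(k))
}

check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > 12) {
    abort("`k` must be a single integer in [1, 12].")
  }
}

#' Canonical k-mer frequency vector of one sequence
#'
#' Every length-`k` window containing only A/C/G/T is counted towards its
#' canonical k-mer; counts are divided by the number of valid windows.
#' Windows containing N (or any ambiguity character) are skipped. A
#' sequence with zero valid windows yields the all-zero vector, and the
#' contig is treated as unprojectable downstream.
#'
#' @param seq A single nucleotide string over A/C/G/T/N.
#' @param k Word size, 1-12.
#' @return Named numeric vector over canonical k-mers summing to 1 (or to
#'   0 when no window is valid).
#' @export
#' @examples
#' kmer_frequencies("AAAAA", 5)[["AAAAA"]]
kmer_frequencies <- function(seq, k) {
  check_k(k)
  k <- as.integer(k)
  counts <- .kmer_counts_matrix(seq, k)
  freq <- counts[1L, ]
  tot <- sum(freq)
  if (tot > 0) freq <- freq / tot
  setNames(freq, .kmer_names(k))
}

# dense canonical count matrix, one row per sequence
.kmer_counts_matrix <- function(seqs, k) {
  fold <- .kmer_fold(k)
  set <- Biostrings::DNAStringSet(seqs)
  raw <- Biostrings::oligonucleotideFrequency(set, width = k,
                                              simplify.as = "matrix")
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  # fold columns 4^k -> canonical D; rowsum over the transposed matrix
  folded <- t(rowsum(t(raw), group = fold$group, reorder = TRUE))
  storage.mode(folded) <- "double"
  folded
}

#' Canonical k-mer frequency matrix of an assembly
#'
#' @param contigs Contig tibble (`id`, `seq`, `length`) from
#'   [read_fasta()] or [generate_mixture()].
#' @param k Word size, 1-12.
#' @return List with `freq` (matrix, one row per contig, rownames = contig
#'   ids, columns = canonical k-mers), and `projectable` (logical vector:
#'   the contig had at least one valid window).
#' @export
kmer_profile <- function(contigs, k) {
  check_k(k)
  k <- as.integer(k)
  n <- nrow(contigs)
  fold <- .kmer_fold(k)
  freq <- matrix(0, nrow = n, ncol = fold$dim)
  block <- max(1L, as.integer(5e7 / 8 / fold$dim))  # cap transient memory
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(n, s + block - 1L)
    freq[idx, ] <- .kmer_counts_matrix(contigs$seq[idx], k)
  }
  tot <- rowSums(freq)
  projectable <- tot > 0
  freq[projectable, ] <- freq[projectable, , drop = FALSE] / tot[projectable]
  rownames(freq) <- contigs$id
  if (fold$dim <= 4096L) colnames(freq) <- .kmer_names(k)
  list(freq = freq, projectable = setNames(projectable, contigs$id))
}

revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}
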