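# Built-in gene caller: maximal ATG-to-stop open reading frames on all six
# frames under the standard code (stops TAA/TAG/TGA). It exists so the
# eukaryotic screen can run without an external gene caller; any tool that
# produces intervals per contig (e.g. prodigal via GFF) can replace it
# through read_genes_gff().

.orf_one_strand <- function(s, min_orf_len) {
  L <- nchar(s)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 2L) next
    pos <- seq(f + 1L, by = 3L, length.out = ncod)      # 1-based codon starts
    cod <- substring(s, pos, pos + 2L)
    is_stop <- cod %in% stops
    is_start <- cod == "ATG"
    if (!any(is_stop) || !any(is_start)) next
    seg <- cumsum(c(FALSE, head(is_stop, -1L)))         # segment id per codon
    stop_idx <- which(is_stop)
    # first ATG in each segment that terminates in a stop
    start_idx <- which(is_start & !is_stop)
    if (!length(start_idx)) next
    first_start <- tapply(start_idx, seg[start_idx], min)
    seg_of_stop <- seg[stop_idx]
    hit <- match(as.character(seg_of_stop), names(first_start))
    keep <- !is.na(hit)
    a <- as.integer(first_start[hit[keep]])             # codon index of ATG
    b <- stop_idx[keep]                                 # codon index of stop
    st <- pos[a] - 1L                                   # 0-based inclusive
    en <- pos[b] + 2L                                   # 0-based exclusive
    len <- en - st
    sel <- len >= min_orf_len
    if (any(sel)) out[[length(out) + 1L]] <- cbind(st[sel], en[sel])
  }
  if (!length(out)) return(matrix(integer(), ncol = 2L))
  do.call(rbind, out)
}

#' Find open reading frames on a contig (built-in gene caller)
#'
#' Scans all six frames for maximal open reading frames (first in-frame
#' ATG to the next stop, stop codon included) of at least `min_orf_len`
#' bases. Intervals are 0-based half-open on the forward strand; minus
#' strand ORFs are reported in forward coordinates with `strand = "-"`.
#' Windows interrupted by N never contain a start or stop codon match and
#' are skipped naturally; an all-N contig yields no genes.
#'
#' @param contigs Contig tibble (`id`, `seq`), or a single contig row.
#' @param min_orf_len Minimum ORF length in bases (>= 60; default 300).
#' @return Tibble `contig_id`, `start`, `end`, `strand`, `gene_id`.
#' @export
call_genes <- function(contigs, min_orf_len = 300L) {
  if (min_orf_len < 60L) abort("`min_orf_len` must be at least 60 bases.")
  rows <- purrr::map(seq_len(nrow(contigs)), function(i) {
    s <- contigs$seq[i]
    L <- nchar(s)
    fwd <- .orf_one_strand(s, min_orf_len)
    rev <- .orf_one_strand(revcomp(s), min_orf_len)
    res <- rbind(
      if (nrow(fwd)) cbind(fwd, 1L) else NULL,
      # map revcomp interval [a, b) back to forward coordinates [L-b, L-a)
      if (nrow(rev)) cbind(L - rev[, 2L], L - rev[, 1L], 0L) else NULL
    )
    if (is.null(res) || !nrow(res)) return(NULL)
    res <- res[order(res[, 1L], res[, 2L]), , drop = FALSE]
    tibble(contig_id = contigs$id[i],
           start = as.integer(res[, 1L]), end = as.integer(res[, 2L]),
           strand = dplyr::if_else(res[, 3L] == 1L, "+", "-"))
  })
  genes <- dplyr::bind_rows(rows)
  if (nrow(genes) == 0L) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  gene_id = character()))
  }
  genes |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::mutate(gene_id = sprintf("%s_g%d", .data$contig_id,
                                    dplyr::row_number())) |>
    dplyr::ungroup()
}

#' Extract gene sequences from contigs
#'
#' Minus-strand genes are reverse-complemented.
#'
#' @param contigs Contig tibble.
#' @param genes Gene table from [call_genes()].
#' @return Contig-shaped tibble (`id` = gene id, `seq`, `length`) usable
#'   as aligner queries.
#' @export
gene_sequences <- function(contigs, genes) {
  seqs <- setNames(contigs$seq, contigs$id)
  s <- substring(seqs[genes$contig_id], genes$start + 1L, genes$end)
  s <- ifelse(genes$strand == "-", revcomp(s), s)
  tibble(id = genes$gene_id, seq = unname(s), length = nchar(s))
}
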