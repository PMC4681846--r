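# Synthetic study material: Markov-chain source genomes with controlled
# GC content, contaminated contig mixtures with truth labels, a mock
# lineage-annotated reference database, and a shared-k-mer mock aligner.
# All generation is deterministic per seed; fixtures are regenerated in
# code, never stored.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic source genome
#'
#' @param lineage Lineage string or `lineage` object for the genome.
#' @param length Genome length in bases (>= 50 kb recommended; required
#'   for calibration-suite genomes).
#' @param gc Stationary GC fraction, in (0.2, 0.8).
#' @param markov_order 0 for i.i.d. bases; 1 adds first-order structure
#'   (run/alternation persistence) with the same stationary composition.
#' @param seed Integer seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(lineage, length, gc, markov_order = 1L, seed = 1L) {
  if (!(gc > 0.2 && gc < 0.8)) abort("`gc` must lie in (0.2, 0.8).")
  if (length < 1) abort("`length` must be positive.")
  if (markov_order < 0) abort("`markov_order` must be >= 0.")
  if (!inherits(lineage, "lineage")) lineage <- parse_lineage(lineage)
  structure(list(lineage = lineage, length = as.integer(length), gc = gc,
                 markov_order = as.integer(markov_order),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome sequence
#'
#' Bases are sampled from a Markov chain whose stationary distribution is
#' strand-symmetric with the requested GC content: with probability
#' `1 - alpha` a position is drawn fresh from the stationary composition;
#' otherwise it copies (probability `beta`, drawn per genome) or
#' complements the previous base. Both moves preserve the stationary
#' composition exactly, so observed GC matches the request to within
#' sampling noise (well inside +/- 0.01 at 100 kb). `markov_order = 0`
#' sets `alpha = 0` (i.i.d.). Deterministic per seed.
#'
#' @param spec A [genome_spec()].
#' @param alpha Persistence probability for the order-1 component.
#' @return A single nucleotide string of length `spec$length`.
#' @export
generate_genome <- function(spec, alpha = 0.5) {
  stopifnot(inherits(spec, "genome_spec"))
  L <- spec$length
  p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  with_seed(spec$seed, {
    if (spec$markov_order == 0L) alpha <- 0
    beta <- stats::runif(1, 0.3, 0.7)     # per-genome run-vs-alternation mix
    u <- stats::runif(L - 1L)
    renew <- c(TRUE, u < (1 - alpha))
    flip <- c(FALSE, !renew[-1L] & (u >= (1 - alpha) + alpha * beta))
    grp <- cumsum(renew)
    fresh <- sample.int(4L, max(grp), replace = TRUE, prob = p)
    # parity of complement moves since the group's renewal position
    cc <- cumsum(flip)
    cc0 <- cc[renew]                       # value at each renewal position
    parity <- (cc - cc0[grp]) %% 2L
    base <- fresh[grp]
    comp <- c(4L, 3L, 2L, 1L)              # A<->T, C<->G
    base[parity == 1L] <- comp[base[parity == 1L]]
    paste(c("A", "C", "G", "T")[base], collapse = "")
  })
}

#' Specify a contaminated synthetic mixture
#'
#' @param target A [genome_spec()] for the target organism.
#' @param contaminants List of `list(spec = genome_spec, fraction = x)`;
#'   fractions of assembly bases, summing to < 1.
#' @param total_bases Total assembly size in bases.
#' @param contig_meanlog,contig_sdlog Lognormal contig-length parameters.
#' @param min_contig Truncation floor for contig lengths (bases).
#' @param seed Integer seed.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(target, contaminants = list(),
                         total_bases = 1e6,
                         contig_meanlog = log(6000), contig_sdlog = 0.7,
                         min_contig = 1000L, seed = 1L) {
  fr <- vapply(contaminants, function(x) x$fraction, numeric(1))
  if (length(fr) && sum(fr) >= 1) {
    abort("Contaminant fractions must sum to < 1.")
  }
  structure(list(target = target, contaminants = contaminants,
                 total_bases = as.integer(total_bases),
                 contig_meanlog = contig_meanlog,
                 contig_sdlog = contig_sdlog,
                 min_contig = as.integer(min_contig),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

# draw contig lengths summing exactly to `budget`
.draw_lengths <- function(budget, meanlog, sdlog, min_len) {
  lens <- integer(0)
  while (sum(lens) < budget) {
    draw <- pmax(min_len, round(rlnorm(16L, meanlog, sdlog)))
    lens <- c(lens, as.integer(draw))
  }
  over <- sum(lens) - budget
  k <- length(lens)
  while (over >= lens[k] - min_len && k > 1L) {   # drop whole contigs
    over <- over - lens[k]
    lens <- lens[-k]
    k <- k - 1L
  }
  lens[k] <- lens[k] - over
  if (lens[k] < min_len && k > 1L) {              # fold remainder into previous
    lens[k - 1L] <- lens[k - 1L] + lens[k]
    lens <- lens[-k]
  }
  as.integer(lens)
}

#' Generate a contaminated assembly with truth labels and a mock reference
#'
#' Contigs are consecutive non-overlapping windows of each source genome,
#' sized to hit the stated base fractions exactly, then shuffled. The
#' mock reference database holds lineage-annotated fragments covering
#' alternating tiles (about half) of each source genome, so the
#' shared-k-mer mock aligner finds nucleotide-level homologs for contigs
#' of every source while contigs from uncovered regions stay
#' alignment-undecided and exercise the composition stage.
#'
#' @param spec A [mixture_spec()].
#' @param ref_fragment Fragment length for the mock reference database.
#' @return List: `contigs` (assembly tibble), `truth` (tibble
#'   `contig_id`, `source`, `lineage`, `truth` in {clean, contaminant}),
#'   `ref_db` (list `seqs`, `lineages`), `target_lineage`.
#' @export
generate_mixture <- function(spec, ref_fragment = 40000L) {
  stopifnot(inherits(spec, "mixture_spec"))
  sources <- c(list(list(spec = spec$target, fraction = NA_real_)),
               spec$contaminants)
  fr_con <- vapply(spec$contaminants, function(x) x$fraction, numeric(1))
  budgets <- as.integer(round(spec$total_bases * c(1 - sum(fr_con), fr_con)))
  tags <- c("tgt", if (length(fr_con))
    sprintf("con%d", seq_along(fr_con)))
  for (i in seq_along(sources)) {
    if (budgets[i] > sources[[i]]$spec$length) {
      abort(sprintf(
        "Requested %d bases from source '%s' but its genome is only %d bases.",
        budgets[i], tags[i], sources[[i]]$spec$length))
    }
  }
  genomes <- lapply(sources, function(s) generate_genome(s$spec))
  with_seed(spec$seed, {
    pieces <- purrr::map(seq_along(sources), function(i) {
      lens <- .draw_lengths(budgets[i], spec$contig_meanlog,
                            spec$contig_sdlog, spec$min_contig)
      # scatter the contigs over the genome without overlap: spread the
      # unused bases over random inter-contig gaps
      slack <- sources[[i]]$spec$length - sum(lens)
      cuts <- sort(stats::runif(length(lens), 0, slack))
      gaps <- floor(c(cuts[1], diff(cuts)))
      starts <- as.integer(cumsum(gaps) + cumsum(c(0L, head(lens, -1L))) + 1L)
      ends <- starts + lens - 1L
      tibble(
        id = sprintf("%s_c%03d", tags[i], seq_along(lens)),
        seq = substring(genomes[[i]], starts, ends),
        length = lens,
        source = tags[i],
        lineage = format_lineage(sources[[i]]$spec$lineage),
        truth = if (i == 1L) "clean" else "contaminant"
      )
    })
    all <- dplyr::bind_rows(pieces)
    all <- all[sample.int(nrow(all)), ]
    frags <- purrr::map(seq_along(sources), function(i) {
      L <- sources[[i]]$spec$length
      starts <- seq(1L, L, by = ref_fragment)
      ends <- pmin(starts + ref_fragment - 1L, L)
      # alternate tiles: the reference covers ~half of each source genome,
      # so some contigs find no homolog and fall to the composition stage
      keep <- (ends - starts + 1L) >= 1000L &
        (seq_along(starts) %% 2L == 1L)
      tibble(
        subject_id = sprintf("ref_%s_f%03d", tags[i],
                             seq_along(starts))[keep],
        seq = substring(genomes[[i]], starts[keep], ends[keep]),
        lineage = format_lineage(sources[[i]]$spec$lineage)
      )
    }) |> dplyr::bind_rows()
    list(
      contigs = tibble(id = all$id, seq = all$seq, length = all$length),
      truth = tibble(contig_id = all$id, source = all$source,
                     lineage = all$lineage, truth = all$truth),
      ref_db = list(
        seqs = tibble(id = frags$subject_id, seq = frags$seq,
                      length = nchar(frags$seq)),
        lineages = tibble(subject_id = frags$subject_id,
                          lineage = frags$lineage)
      ),
      target_lineage = sources[[1]]$spec$lineage
    )
  })
}

#' Write a generated mixture to disk
#'
#' @param mix Output of [generate_mixture()].
#' @param dir Output directory (created if needed): `assembly.fna`,
#'   `truth.tsv`, `refdb/reference.fna`, `refdb/lineages.tsv`.
#' @return `dir`, invisibly.
#' @export
write_mixture <- function(mix, dir) {
  dir.create(file.path(dir, "refdb"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(mix$contigs, file.path(dir, "assembly.fna"))
  write_tsv_plain(mix$truth, file.path(dir, "truth.tsv"))
  write_fasta(mix$ref_db$seqs, file.path(dir, "refdb", "reference.fna"))
  write.table(mix$ref_db$lineages, file.path(dir, "refdb", "lineages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(dir)
}

.canonical_strings <- function(x) pmin(x, revcomp(x))

.window_kmers <- function(seq, k, dedup = TRUE) {
  L <- nchar(seq)
  if (L < k) return(character())
  w <- substring(seq, 1:(L - k + 1L), k:L)
  w <- w[!grepl("N", w, fixed = TRUE)]
  w <- .canonical_strings(w)
  if (dedup) unique(w) else w
}

#' Shared-k-mer mock aligner
#'
#' Reports a hit between a query contig and a reference sequence when
#' they share at least `min_shared` distinct canonical 31-mers, and
#' synthesises the 12-column alignment fields from the shared-window
#' count (`aln_len = shared + k - 1`, identity 1, bitscore
#' `2 * aln_len`). It exists to exercise the homology logic without an
#' external aligner; any tool emitting the standard 12-column tabular
#' format can replace it via [read_alignment_table()]. Canonical k-mers
#' make it strand-insensitive, like a real nucleotide aligner.
#'
#' @param query Contig tibble (assembly contigs or gene sequences).
#' @param ref_db Reference list with `seqs` and `lineages` (see
#'   [generate_mixture()]), or a seqs tibble plus `lineages=`.
#' @param k Word size (default 31).
#' @param min_shared Minimum count of distinct shared canonical words.
#' @return Hit tibble in the same shape as [read_alignment_table()].
#' @export
align_shared_kmers <- function(query, ref_db, k = 31L, min_shared = 5L) {
  seqs <- ref_db$seqs
  lineages <- ref_db$lineages
  ref_kmers <- purrr::map(seqs$seq, .window_kmers, k = k)
  ref_vec <- unlist(ref_kmers, use.names = FALSE)
  ref_subj <- rep.int(seq_len(nrow(seqs)), lengths(ref_kmers))
  q_kmers <- purrr::map(query$seq, .window_kmers, k = k)
  q_vec <- unlist(q_kmers, use.names = FALSE)
  q_idx <- rep.int(seq_len(nrow(query)), lengths(q_kmers))
  empty <- tibble(query_id = character(), subject_id = character(),
                  identity = numeric(), aln_len = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  qstart = integer(), qend = integer(), sstart = integer(),
                  send = integer(), evalue = numeric(),
                  bitscore = numeric(), subject_lineage = character())
  if (!length(q_vec) || !length(ref_vec)) return(empty)
  mi <- match(q_vec, ref_vec)
  sel <- !is.na(mi)
  if (!any(sel)) return(empty)
  ns <- nrow(seqs)
  enc <- (q_idx[sel] - 1L) * ns + ref_subj[mi[sel]]
  counts <- tabulate(enc, nbins = nrow(query) * ns)
  pair <- which(counts >= min_shared)
  if (!length(pair)) return(empty)
  qi <- (pair - 1L) %/% ns + 1L
  si <- (pair - 1L) %% ns + 1L
  shared <- counts[pair]
  aln_len <- as.integer(shared + k - 1L)
  hits <- tibble(
    query_id = query$id[qi],
    subject_id = seqs$id[si],
    identity = 1.0,
    aln_len = aln_len,
    mismatches = 0L, gap_opens = 0L,
    qstart = 1L, qend = aln_len, sstart = 1L, send = aln_len,
    evalue = 0, bitscore = 2 * aln_len
  )
  dplyr::left_join(hits, lineages, by = "subject_id") |>
    dplyr::rename(subject_lineage = "lineage")
}
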