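test_that("generated genomes hit the requested GC and are seed-deterministic", {
  for (gc in c(0.30, 0.50, 0.65)) {
    g <- generate_genome(genome_spec(lin_target, 1e5, gc = gc, seed = 41))
    obs <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / nchar(g)
    expect_lt(abs(obs - gc), 0.01)
  }
  spec <- genome_spec(lin_target, 5e4, gc = 0.42, seed = 5)
  expect_identical(generate_genome(spec), generate_genome(spec))
  # order-0 chains are also exactly seeded
  spec0 <- genome_spec(lin_target, 2e4, gc = 0.42, markov_order = 0,
                       seed = 5)
  expect_identical(generate_genome(spec0), generate_genome(spec0))
})

test_that("genomes of divergent GC separate in 5-mer space beyond intra-genome spread", {
  lo <- generate_genome(genome_spec(lin_target, 2e5, gc = 0.30, seed = 61))
  hi <- generate_genome(genome_spec(lin_other_phy, 2e5, gc = 0.65,
                                    seed = 62))
  chop <- function(g, tag) {
    starts <- seq(1, nchar(g) - 9999, by = 10000)[1:10]
    tibble::tibble(id = sprintf("%s%02d", tag, seq_along(starts)),
                   seq = substring(g, starts, starts + 9999),
                   length = 10000L)
  }
  prof <- kmer_profile(dplyr::bind_rows(chop(lo, "lo"), chop(hi, "hi")), 5)
  centroid <- function(rows) colMeans(prof$freq[rows, , drop = FALSE])
  c_lo <- centroid(1:10); c_hi <- centroid(11:20)
  between <- sqrt(sum((c_lo - c_hi)^2))
  spread <- max(sqrt(rowSums(sweep(prof$freq[1:10, ], 2, c_lo)^2)),
                sqrt(rowSums(sweep(prof$freq[11:20, ], 2, c_hi)^2)))
  expect_gt(between, spread)
})

test_that("mixtures hit the requested contamination fraction and account for every base", {
  mix <- generate_mixture(mixture_spec(
    genome_spec(lin_target, 1.2e6, gc = 0.40, seed = 71),
    list(list(spec = genome_spec(lin_other_phy, 3e5, gc = 0.60, seed = 72),
              fraction = 0.10)),
    total_bases = 1e6, seed = 73))
  con_bases <- sum(mix$contigs$length[mix$truth$truth == "contaminant"])
  expect_lt(abs(con_bases - 1e5), 1e4)          # within 1% of the assembly
  expect_equal(sum(mix$contigs$length), 1e6)    # clean + contaminant == total
  expect_setequal(mix$truth$contig_id, mix$contigs$id)
  expect_true(all(mix$contigs$length >= 1000L))

  clean_only <- generate_mixture(mixture_spec(
    genome_spec(lin_target, 2e5, gc = 0.40, seed = 74),
    total_bases = 1e5, seed = 75))
  expect_true(all(clean_only$truth$truth == "clean"))

  expect_error(generate_mixture(mixture_spec(
    genome_spec(lin_target, 5e4, gc = 0.40, seed = 76),
    total_bases = 1e5, seed = 77)), "exceed|only")
})

test_that("mixtures are deterministic per seed and write cleanly to disk", {
  sp <- mixture_spec(
    genome_spec(lin_target, 1e5, gc = 0.40, seed = 81),
    list(list(spec = genome_spec(lin_other_phy, 1e5, gc = 0.60, seed = 82),
              fraction = 0.2)),
    total_bases = 5e4, seed = 83)
  m1 <- generate_mixture(sp)
  m2 <- generate_mixture(sp)
  expect_identical(m1, m2)

  dir <- withr::local_tempdir()
  write_mixture(m1, dir)
  back <- read_fasta(file.path(dir, "assembly.fna"))
  expect_equal(back, m1$contigs)
  lin <- read_lineage_table(file.path(dir, "refdb", "lineages.tsv"))
  expect_setequal(lin$subject_id, m1$ref_db$lineages$subject_id)
})

test_that("the mock aligner only links contigs to their own source genome", {
  mix <- generate_mixture(mixture_spec(
    genome_spec(lin_target, 1e5, gc = 0.40, seed = 91),
    list(list(spec = genome_spec(lin_other_phy, 1e5, gc = 0.60, seed = 92),
              fraction = 0.3)),
    total_bases = 6e4, seed = 93))
  hits <- align_shared_kmers(mix$contigs, mix$ref_db)
  expect_gt(nrow(hits), 0)
  src <- setNames(mix$truth$source, mix$truth$contig_id)
  subj_src <- sub("^ref_([a-z0-9]+)_f.*$", "\\1", hits$subject_id)
  expect_true(all(src[hits$query_id] == subj_src))
  # hence homology CLEAN labels can only arise for target-source contigs
  lab <- classify_by_homology(mix$contigs, hits,
                              parse_lineage(lin_target))
  clean_ids <- lab$contig_id[lab$label == "CLEAN"]
  expect_true(all(src[clean_ids] == "tgt"))
})

test_that("the mock aligner is strand-insensitive", {
  mix <- generate_mixture(mixture_spec(
    genome_spec(lin_target, 8e4, gc = 0.45, seed = 95),
    total_bases = 3e4, seed = 96))
  hits_f <- align_shared_kmers(mix$contigs, mix$ref_db)
  rc <- mix$contigs
  rc$seq <- rc_string(rc$seq)
  hits_r <- align_shared_kmers(rc, mix$ref_db)
  key <- function(h) dplyr::arrange(h[, c("query_id", "subject_id",
                                          "aln_len")],
                                    .data$query_id, .data$subject_id)
  expect_equal(key(hits_f), key(hits_r))
})

test_that("a reduced calibration grid reproduces deterministically with sane trade-offs", {
  run <- function() calibration_suite(
    seed = 2026, candidate_f = c(1, 2, 3),
    contam_fracs = c(0.10, 0.25), gc_gaps = c(0.20, 0.30), n_seeds = 1,
    total_bases = 1e5, genome_length = 1.5e5)
  a <- run()
  expect_identical(a, run())
  med <- a$medians
  # sensitivity grows with the factor; specificity never increases
  expect_true(all(diff(med$median_sensitivity) >= -1e-12))
  expect_true(all(diff(med$median_specificity) <= 1e-12))
  expect_equal(a$factor, max(med$f[med$median_specificity >= 0.8]))
})
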