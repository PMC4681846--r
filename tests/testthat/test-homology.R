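target <- parse_lineage(lin_target)

test_that("best-hit classification yields CLEAN / CONTAMINANT / UNDECIDED", {
  contigs <- tibble::tibble(id = c("c1", "c2", "c3"),
                            seq = "ACGT", length = 5000L)
  hits <- dplyr::bind_rows(
    mk_hit("c1", "refA", lin_target, bitscore = 900),
    mk_hit("c1", "refB", lin_other_phy, bitscore = 100),
    mk_hit("c3", "refB", lin_other_phy, bitscore = 800, identity = 0.99))
  lab <- classify_by_homology(contigs, hits, target)
  expect_equal(lab$label, c("CLEAN", "UNDECIDED", "CONTAMINANT"))
  expect_equal(lab$decided_at_rank[1], "species")
  expect_true(is.na(lab$decided_at_rank[2]))
  # every contig appears exactly once: the label set partitions the assembly
  expect_equal(lab$contig_id, contigs$id)
})

test_that("agreement at the required rank decides CLEAN; shallower agreement decides CONTAMINANT", {
  contigs <- tibble::tibble(id = c("c1", "c2"), seq = "A", length = 1000L)
  same_class <- "Bacteria;PhylA;ClassA;OtherOrd;OtherFam;OtherGen;other"
  same_phylum <- "Bacteria;PhylA;OtherClass"
  hits <- dplyr::bind_rows(mk_hit("c1", "r1", same_class),
                           mk_hit("c2", "r2", same_phylum))
  lab <- classify_by_homology(contigs, hits, target)
  expect_equal(lab$label, c("CLEAN", "CONTAMINANT"))
  expect_equal(lab$decided_at_rank[1], "class")
})

test_that("sub-threshold hits do not qualify and tie-breaking is total", {
  contigs <- tibble::tibble(id = "c1", seq = "A", length = 1000L)
  weak <- dplyr::bind_rows(
    mk_hit("c1", "r1", lin_other_phy, identity = 0.90),   # below identity
    mk_hit("c1", "r2", lin_other_phy, aln_len = 100))     # below length
  expect_equal(classify_by_homology(contigs, weak, target)$label,
               "UNDECIDED")

  # equal bitscore/identity/length: lexicographically smallest subject wins
  tie <- dplyr::bind_rows(mk_hit("c1", "zzz", lin_other_phy),
                          mk_hit("c1", "aaa", lin_target))
  for (perm in list(1:2, 2:1)) {
    lab <- classify_by_homology(contigs, tie[perm, ], target)
    expect_equal(lab$subject_id, "aaa")
    expect_equal(lab$label, "CLEAN")
  }
})

test_that("hit-order permutations never change labels", {
  set.seed(31)
  contigs <- tibble::tibble(id = sprintf("c%d", 1:6), seq = "A",
                            length = 2000L)
  hits <- dplyr::bind_rows(purrr::map(1:30, function(i) {
    mk_hit(sample(contigs$id, 1), sprintf("r%d", sample(9, 1)),
           sample(c(lin_target, lin_other_phy), 1),
           bitscore = sample(c(500, 700, 900), 1),
           identity = sample(c(0.96, 0.99), 1),
           aln_len = sample(c(300, 600), 1))
  }))
  ref <- classify_by_homology(contigs, hits, target)
  for (i in 1:5) {
    perm <- classify_by_homology(contigs, hits[sample(nrow(hits)), ],
                                 target)
    expect_identical(perm, ref)
  }
})

test_that("raising min_identity only moves contigs towards UNDECIDED", {
  set.seed(32)
  contigs <- tibble::tibble(id = sprintf("c%d", 1:8), seq = "A",
                            length = 2000L)
  hits <- dplyr::bind_rows(purrr::map(1:40, function(i) {
    mk_hit(sample(contigs$id, 1), sprintf("r%d", i),
           sample(c(lin_target, lin_other_phy), 1),
           bitscore = runif(1, 100, 1000),
           identity = runif(1, 0.95, 1.0))
  }))
  loose <- classify_by_homology(contigs, hits, target,
                                prodege_config(min_identity = 0.95))
  strict <- classify_by_homology(contigs, hits, target,
                                 prodege_config(min_identity = 0.99))
  for (i in seq_len(nrow(contigs))) {
    if (strict$label[i] != "UNDECIDED") {
      expect_equal(strict$label[i], loose$label[i])
    }
  }
})

test_that("a target-only reference produces no CONTAMINANT labels", {
  set.seed(33)
  contigs <- tibble::tibble(id = sprintf("c%d", 1:10), seq = "A",
                            length = 2000L)
  hits <- dplyr::bind_rows(purrr::map(1:25, function(i) {
    mk_hit(sample(contigs$id, 1), sprintf("r%d", i), lin_target,
           bitscore = runif(1, 100, 1000))
  }))
  expect_false(any(classify_by_homology(contigs, hits, target)$label ==
                     "CONTAMINANT"))
})

test_that("a shallow target lineage is refused", {
  contigs <- tibble::tibble(id = "c1", seq = "A", length = 100L)
  expect_error(
    classify_by_homology(contigs, mk_hit("c1", "r", lin_target),
                         parse_lineage("Bacteria;PhylA")),
    "9-mer")
})

test_that("the eukaryote screen needs a strict majority of hit-bearing genes", {
  genes <- tibble::tibble(contig_id = rep(c("c1", "c2", "c3"), each = 3),
                          start = 0L, end = 300L, strand = "+",
                          gene_id = sprintf("g%d", 1:9))
  hits <- dplyr::bind_rows(
    mk_hit("g1", "e1", lin_euk), mk_hit("g2", "e1", lin_euk),
    # c2: one euk, one prokaryote best hit -> tie, not flagged
    mk_hit("g4", "e1", lin_euk), mk_hit("g5", "p1", lin_other_phy))
  flagged <- screen_eukaryotic(genes, hits)
  expect_equal(flagged, "c1")

  expect_equal(screen_eukaryotic(genes, hits[0, ]), character())

  # the per-gene BEST hit decides: a stronger prokaryote hit masks a euk one
  masked <- dplyr::bind_rows(
    mk_hit("g1", "e1", lin_euk, bitscore = 200),
    mk_hit("g1", "p1", lin_other_phy, bitscore = 900))
  expect_equal(screen_eukaryotic(genes, masked), character())
})

test_that("bin confidence needs count, coverage and phylum dominance", {
  mk_labels <- function(labels, lineages = NA_character_) {
    tibble::tibble(contig_id = sprintf("c%d", seq_along(labels)),
                   label = labels,
                   decided_at_rank = NA_character_,
                   subject_id = ifelse(labels == "UNDECIDED",
                                       NA_character_, "r"),
                   subject_lineage = lineages,
                   identity = 0.99, aln_len = 500L, bitscore = 500)
  }
  contigs_eq <- function(n, len = 1000L)
    tibble::tibble(id = sprintf("c%d", 1:n), seq = "A", length = len)

  # no clean contigs
  expect_false(confident_target_bin_exists(
    mk_labels(rep("UNDECIDED", 5)), contigs_eq(5)))

  # 5 clean covering most bases, scattered small contaminants
  lab <- mk_labels(c(rep("CLEAN", 5), rep("CONTAMINANT", 2), "UNDECIDED"),
                   c(rep(NA, 5), lin_other_phy,
                     "Bacteria;PhylC;ClassC", NA))
  contigs <- tibble::tibble(id = sprintf("c%d", 1:8), seq = "A",
                            length = c(rep(12000L, 5), 2000L, 2000L,
                                       3000L))
  expect_true(confident_target_bin_exists(lab, contigs))

  # clean bin small and one contaminant phylum dominates
  lab2 <- mk_labels(c(rep("CLEAN", 3), rep("CONTAMINANT", 2), "UNDECIDED"),
                    c(rep(NA, 3), lin_other_phy, lin_other_phy, NA))
  contigs2 <- tibble::tibble(id = sprintf("c%d", 1:6), seq = "A",
                             length = c(5000L, 5000L, 5000L, 20000L,
                                        20000L, 45000L))
  expect_false(confident_target_bin_exists(lab2, contigs2))

  # fewer than 3 clean contigs
  expect_false(confident_target_bin_exists(
    mk_labels(c("CLEAN", "CLEAN", "UNDECIDED")), contigs_eq(3)))
})
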