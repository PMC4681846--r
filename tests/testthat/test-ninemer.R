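# Two-source mixtures at the scale the 9-mer mode is meant for (tens of
# contigs, several kb each). Composition placement of individual short
# contigs is noisy by nature, so assertions are base-weighted -- the
# quantity the cutoff is calibrated on -- not per-contig exactness.
mk_two_source <- function(frac, seed = 101, total = 4e5) {
  generate_mixture(mixture_spec(
    genome_spec(lin_target, 6e5, gc = 0.35, seed = seed),
    list(list(spec = genome_spec(lin_other_phy, 5e5, gc = 0.65,
                                 seed = seed + 1),
              fraction = frac)),
    total_bases = total, contig_meanlog = log(8000), seed = seed + 2))
}

nb_eval <- function(mix, nb, swap = FALSE) {
  tr <- mix$truth
  if (swap) tr$truth <- ifelse(tr$truth == "clean", "contaminant", "clean")
  glance(score_run(
    tibble::tibble(
      contig_id = nb$labels$contig_id,
      length = mix$contigs$length[match(nb$labels$contig_id,
                                        mix$contigs$id)],
      label = nb$labels$label),
    tr))
}

test_that("separated clusters classify at the calibrated rates with the clean bin as target", {
  mix <- mk_two_source(0.25)
  nb <- ninemer_binning(mix$contigs, prodege_config(seed = 1))
  g <- nb_eval(mix, nb)
  expect_gte(g$specificity, 0.8)          # the pre-calibration target
  expect_gte(g$sensitivity, 0.9)
  # the presumed target bin (largest by bases) is entirely truly-clean
  d <- dplyr::inner_join(nb$labels, mix$truth, by = "contig_id")
  d$len <- mix$contigs$length[match(d$contig_id, mix$contigs$id)]
  binned <- d[!is.na(d$bin), ]
  bin_bases <- tapply(binned$len, binned$bin, sum)
  target_bin <- as.integer(names(bin_bases)[which.max(bin_bases)])
  expect_true(all(binned$truth[binned$bin == target_bin] == "clean"))
  expect_equal(nb$cutoff$source, "PRECALIBRATED")
  expect_equal(nb$cutoff$radius, nb$eps * ninemer_precalibrated_factor())
})

test_that("a single-source assembly keeps nearly all bases in the target bin", {
  mix <- generate_mixture(mixture_spec(
    genome_spec(lin_target, 6e5, gc = 0.45, seed = 7),
    total_bases = 4e5, contig_meanlog = log(8000), seed = 8))
  nb <- ninemer_binning(mix$contigs, prodege_config(seed = 1))
  clean_bases <- sum(mix$contigs$length[match(
    nb$labels$contig_id[nb$labels$label == "CLEAN"], mix$contigs$id)])
  expect_gte(clean_bases / sum(mix$contigs$length), 0.9)
  # contigs sharing the target bin are all within the radius
  tb <- nb$labels$bin[match(nb$labels$contig_id[
    which.min(nb$labels$distance)], nb$labels$contig_id)]
  in_target <- nb$labels[!is.na(nb$labels$bin) & nb$labels$bin == tb, ]
  expect_true(all(in_target$label == "CLEAN"))
})

test_that("majority contamination inverts the labels (largest-bin heuristic)", {
  # 65% of bases come from the contaminant: it becomes the presumed
  # target, so the labels score well against the SWAPPED truth
  mix <- mk_two_source(0.65, seed = 131)
  nb <- ninemer_binning(mix$contigs, prodege_config(seed = 1))
  g_swapped <- nb_eval(mix, nb, swap = TRUE)
  expect_gte(g_swapped$specificity, 0.8)
  expect_gte(g_swapped$sensitivity, 0.8)
  # and poorly against the real truth: most truly-clean bases are rejected
  g <- nb_eval(mix, nb)
  expect_lt(g$sensitivity, 0.2)
})

test_that("a user-supplied cutoff replaces the pre-calibrated radius", {
  mix <- mk_two_source(0.25, seed = 141)
  nb <- ninemer_binning(mix$contigs,
                        prodege_config(seed = 1, user_cutoff = 1e-6))
  expect_equal(nb$cutoff$source, "USER")
  expect_equal(nb$cutoff$radius, 1e-6)
  # a vanishing radius keeps only points at the centroid
  expect_gt(sum(nb$labels$label == "CONTAMINANT"),
            sum(mix$truth$truth == "contaminant"))
})

test_that("one projectable contig cannot be binned and is flagged", {
  contigs <- tibble::tibble(
    id = c("a", "b"),
    seq = c(strrep("ACGTGCA", 300), strrep("N", 2100)),
    length = 2100L)
  nb <- ninemer_binning(contigs, prodege_config(seed = 1))
  expect_true(all(nb$labels$label == "CLEAN"))
  expect_match(nb$warning, "insufficient")
})

test_that("binning is deterministic and contig-order invariant", {
  mix <- mk_two_source(0.25, seed = 151, total = 2.5e5)
  cfg <- prodege_config(seed = 9)
  a <- ninemer_binning(mix$contigs, cfg)
  b <- ninemer_binning(mix$contigs, cfg)
  expect_identical(a$labels, b$labels)
  set.seed(42)
  perm <- sample(nrow(mix$contigs))
  c2 <- ninemer_binning(mix$contigs[perm, ], cfg)
  j <- match(a$labels$contig_id, c2$labels$contig_id)
  expect_equal(a$labels$label, c2$labels$label[j])
})
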