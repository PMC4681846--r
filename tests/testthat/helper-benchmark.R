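# The synthetic benchmark mixture used by the end-to-end tests:
# GC 0.38 target + GC 0.62 contaminant, 1 Mb assembly, 10% contamination
# by bases, mock reference DB, seed 42. Built lazily and cached so the
# several tests that exercise it pay for generation and the pipeline runs
# only once each.

.bench <- new.env(parent = emptyenv())

bench_mix <- function() {
  if (is.null(.bench$mix)) {
    tgt <- genome_spec(lin_target, 1.4e6, gc = 0.38, seed = 11)
    con <- genome_spec(lin_other_phy, 4e5, gc = 0.62, seed = 12)
    .bench$mix <- generate_mixture(mixture_spec(
      tgt, list(list(spec = con, fraction = 0.10)),
      total_bases = 1e6, seed = 42))
  }
  .bench$mix
}

bench_config <- function() prodege_config(seed = 42)

bench_run5 <- function() {
  if (is.null(.bench$run5)) {
    mix <- bench_mix()
    .bench$run5 <- run_prodege(mix$contigs, mix$target_lineage,
                               ref_db = mix$ref_db,
                               config = bench_config())
  }
  .bench$run5
}

bench_run9 <- function() {
  if (is.null(.bench$run9)) {
    mix <- bench_mix()
    .bench$run9 <- run_prodege(mix$contigs, "Bacteria",
                               config = bench_config())
  }
  .bench$run9
}
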