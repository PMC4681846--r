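# prodege

Fully automated decontamination of draft genome assemblies.

Single amplified genomes (SAGs), metagenome-assembled genomes and even
isolate assemblies carry contigs from non-target organisms — DNA from the
environmental sample, the amplification chemistry, or the sequencing
process. Screening them by hand costs expert hours per megabase. This
package labels every contig of a draft assembly **CLEAN** (target
organism) or **CONTAMINANT**, with no manual steps, calibrated for high
specificity so that contaminant sequence is kept out of downstream
databases and analyses. It is aimed at microbial genomics groups running
QC over many assemblies at a time.

## Method

Two signals are combined:

1. **Taxonomy-guided nucleotide homology.** Contigs are aligned against a
   lineage-annotated reference (any aligner emitting the standard
   12-column tabular format). Each contig's best hit — highest bitscore,
   with total tie-breaks — decides it: agreement with the declared target
   lineage at class rank or deeper ⇒ CLEAN; disagreement ⇒ CONTAMINANT;
   no qualifying hit ⇒ UNDECIDED. Eukaryotic contamination is flagged at
   the gene level when a strict majority of a contig's hit-bearing ORFs
   align to eukaryotes.
2. **k-mer composition PCA.** Contigs are embedded by canonical
   (strand-pooled) k-mer frequency vectors and projected onto the first
   three principal components. In the homology-calibrated path, the
   stage-1 labels fit a clean-centroid distance cutoff in 5-mer space:
   the radius is the largest one keeping the base-weighted fraction of
   contaminant calibration points inside it at or below
   `1 − target_specificity` (default 0.8). It then classifies the
   UNDECIDED contigs. When taxonomy is shallower than class, no reference
   is available, or no confident target bin emerges, a taxonomy-free
   9-mer mode bins all contigs by single-linkage in PC space, presumes
   the largest bin (by bases) is the target, and applies a pre-calibrated
   cutoff (radius = 4.0 × the neighbour-linking distance, derived for
   ≥ 80% median base-weighted specificity on a synthetic calibration
   grid).

A deterministic synthetic-data module (Markov-chain genomes with
controlled GC, contaminated mixtures with truth labels, a mock
lineage-annotated reference database and a shared-k-mer mock aligner)
makes every stage testable without downloads, and an evaluation module
scores runs with the protocol's base- and contig-weighted sensitivity
(clean bases retained), specificity (contaminant bases removed) and
accuracy.

## Worked example

```r
library(prodege)

tgt <- genome_spec("Bacteria;PhylA;ClassA;OrdA;FamA;GenA;speciesA",
                   1.4e6, gc = 0.38, seed = 11)
con <- genome_spec("Bacteria;PhylB;ClassB;OrdB;FamB;GenB;speciesB",
                   4e5, gc = 0.62, seed = 12)
mix <- generate_mixture(mixture_spec(
  tgt, list(list(spec = con, fraction = 0.10)),
  total_bases = 1e6, seed = 42))

report <- run_prodege(mix$contigs, mix$target_lineage,
                      ref_db = mix$ref_db,
                      config = prodege_config(seed = 42))
report
#> <prodege_report> mode HOMOLOGY_5MER, 133 contigs (1000000 bases)
#>   clean:         119 contigs     907161 bases
#>   contaminant:    14 contigs      92839 bases
#>   cutoff: 0.0688678 (CALIBRATED)

glance(score_run(report, mix$truth))
#> # A tibble: 1 × 4
#>   sensitivity specificity accuracy n_flags
#>         <dbl>       <dbl>    <dbl>   <int>
#> 1           1       0.928    0.993       0
```

The run chose the homology-calibrated path, decided 82 contigs by
alignment and the remaining 51 by the calibrated 5-mer distance; every
truly-clean base was retained (sensitivity 1.0) and 92.8% of contaminant
bases were removed (specificity). `tidy(report)` gives the per-contig
table (label, deciding stage, best hit, PC distance, flags),
`autoplot(report)` the PC1/PC2 projection with the cutoff circle, and
`run_prodege(..., out_dir = "out")` writes `clean.fna`,
`contaminant.fna`, `report.tsv`, `summary.txt` and `projection.tsv`.

A thin command-line wrapper ships in `inst/cli/prodege.R`
(`run`, `simulate`, `evaluate`, `calibrate` subcommands).

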