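# Versioned constants.
#
# .NINEMER_FACTOR is the pre-calibrated multiplier for the 9-mer-only
# mode's distance cutoff, chosen as the largest candidate whose median
# base-weighted specificity across the synthetic calibration grid
# (contamination {5, 10, 25, 40}%, GC gaps {10, 20, 30} points, 3 seeds
# each, master seed 20150609) is >= 0.80. Regenerate with
# scripts/calibrate_ninemer.R; the grid table is stored at
# inst/extdata/ninemer_calibration.tsv.
.NINEMER_FACTOR <- 4.0
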