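# mirtail

Quantification of miRNA 3′ mono-adenylation from small RNA-seq, plus the
qPCR-side analyses that typically accompany it: U6-normalized 2^−ΔΔCt
miRNome screens for "downregulated-and-restored" miRNAs, 2^−ΔCt
quantification of circularization RT-qPCR assays, and standard plate-assay
formulas (LDH cytotoxicity, dual-luciferase, control-mean normalization).

## Who this is for

Non-canonical poly(A) polymerases such as PAPD5 (TENT4B) add a single
non-templated adenosine to the 3′ end of mature miRNAs, marking them for
3′-to-5′ trimming and degradation. Groups studying this regulation need to
measure, per miRNA and per sample, what fraction of molecules carry the
extra A — and to connect that to expression changes seen on qPCR panels.
`mirtail` packages that analysis as tested, seed-reproducible R functions
with a file-based CLI, and ships a ground-truth simulator so every stage can
be validated without touching external data.

## The core statistic

Reads are assigned by exact (configurable-Hamming) full-length comparison
against two references built from the same mature miRNA FASTA:

* **canonical**: the mature sequence itself;
* **adenylated**: the mature sequence plus one terminal `A`.

For miRNAs whose adenylated counts exceed a strict threshold (default
`> 100` summed across samples), the per-sample adenylation level is

```
adenylation level (%) = adenylated / (adenylated + canonical) × 100
```

Conditions are compared per miRNA by one-way ANOVA followed by Fisher's LSD
post hoc test (pairwise t tests on the pooled within-group mean square, no
multiplicity adjustment). On the qPCR side, relative expression is
2^−ΔΔCt with ΔCt = Ct_target − Ct_internal-control and ΔΔCt normalized to
the control-sample-averaged ΔCt; the screen keeps targets whose disease-group
fold is ≤ 0.8× control **and** whose knockdown-group fold returns to within
[0.8, 1.25]× control (both thresholds configurable and echoed in the output
header).

## Worked example

```r
library(mirtail)

ref <- generate_reference(n_mirnas = 12, seed = 42)
cfg <- sim_config(
  samples = data.frame(
    sample_id = c("ctl_1","ctl_2","ctl_3","oe_1","oe_2","oe_3"),
    condition = rep(c("ctl","oe"), each = 3),
    reads     = 10000L),
  adenylation_prob = c(ctl = 0.05, oe = 0.25),  # overexpression raises tailing
  seed = 42)
sim    <- simulate_reads(ref, cfg)
counts <- count_reads(sim, ref)
counts
#> count_table: 12 miRNAs x 6 samples
#> per-sample totals:
#>  sample assigned ambiguous unassigned untrimmed total
#>   ctl_1    10000         0          0         0 10000
#>   ...

lvl <- adenylation_levels(counts, threshold = 100)
round(lvl[1:3, ], 2)
#>             ctl_1 ctl_2 ctl_3  oe_1  oe_2  oe_3
#> sim-miR-001  4.67  5.37  5.46 23.84 24.97 23.94
#> sim-miR-002  4.65  5.66  4.37 28.55 24.55 24.72
#> sim-miR-003  4.58  5.14  4.70 27.06 24.62 23.30

cmp <- compare_adenylation(lvl, setNames(cfg$samples$condition,
                                         cfg$samples$sample_id))
head(cmp$results[, c("mirna_id","F","p","mean.ctl","mean.oe","significant")], 3)
#>      mirna_id         F            p mean.ctl  mean.oe significant
#> 1 sim-miR-001 1880.8885 1.690003e-06 5.168749 24.24755        TRUE
#> 2 sim-miR-002  237.5334 1.034213e-04 4.895551 25.94107        TRUE
#> 3 sim-miR-003  327.7422 5.473985e-05 4.808178 24.99730        TRUE
```

The simulated control condition tails ~5% of molecules and the
overexpression condition ~25%; the recovered levels sit on those design
values and every miRNA is (correctly) flagged at α = 0.05.

## Command-line pipeline

`inst/cli/mirtail.R` dispatches five stages that communicate through plain
text files:

```sh
Rscript inst/cli/mirtail.R simulate    --config cfg.json --outdir sim/
Rscript inst/cli/mirtail.R count       --reference sim/reference.fa \
        --samples manifest.tsv --out counts.tsv [--adapter SEQ]
Rscript inst/cli/mirtail.R adenylation --counts counts.tsv \
        --design design.csv --out aden.tsv --threshold 100 --mode sum
Rscript inst/cli/mirtail.R screen      --ct panel.csv --design design.csv \
        --control-gene U6 --down 0.8 --restore-low 0.8 --restore-high 1.25 \
        --out screen.tsv
Rscript inst/cli/mirtail.R assays      --mode ldh --in plate.csv --out ldh.csv
```

Every stage rerun with the same seed/config produces byte-identical output.

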