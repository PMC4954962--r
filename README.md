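# inclusionscreen

Analysis pipeline for genome-wide **high-content imaging screens of protein
inclusion (aggregate) formation in yeast**, modelled on screens of
dsRed-tagged synphilin-1 — a Lewy-body component — expressed across the
*S. cerevisiae* deletion and temperature-sensitive allele collections. It is
written for screen analysts who have plates of 16-bit fluorescence images
(plus growth curves, an annotation table and an interaction edge list) and
need the full chain from pixels to an annotated hit network, and for method
developers who want every stage exercisable against synthetic data with
planted ground truth.

## What it computes

**Phenotype.** For each well, the screen statistic is the percentage of
signal-bearing cells that carry an inclusion. Cells are isolated by the
intensity-difference rule *pixel − local background ≥ 300* grayscale units;
inclusions by *pixel − cell diffuse level ≥ 400* (both thresholds
configurable); the two masks combine into per-cell records and per-well
phenotypes `(n_cells, pct_inclusion, mean_cell_intensity)`.

**Hit calling.** Strain vs wild-type, with replicate wells, by the
two-sample pooled-variance Student's *t*:

- `p_inclusion ≤ 0.05` on the inclusion percentages, and
- effect ≥ 25% (relative to WT by default; percentage-point mode available), and
- `p_intensity > 0.05` on the intensity control — otherwise the strain is
  routed to `expression_confounded`, since a change in expression level can
  itself change inclusion counts.

Reported values are WT-anchored: WT = 50%, a strain at half the WT
percentage prints 25.

**Downstream.** Hypergeometric term enrichment
`P(X ≥ k) = Σ C(K,i)·C(N−K,n−i)/C(N,n)` against the deduplicated array gene
universe with Bonferroni (or simulation) correction; a physical-interaction
hit network (genetic edges filtered out) whose connected components are the
modules; and cytotoxicity as the excess generation-time increase
`ΔΔg = (g_SY1 − g_control)_mutant − (g_SY1 − g_control)_WT` from 72 h OD
curves sampled every 30 min, tested with the same Student's *t*.

All formats are plain: TIFF images (a built-in 16-bit grayscale
reader/writer), CSV plate maps, TSV tables, GAF or two-column annotation,
BioGRID-style or plain edge lists, wide growth CSVs, GraphML/SIF exports.

## Worked example

Simulate a 4-strain × 3-replicate plate with planted truth, quantify it,
and call hits. `yke2d` is planted as a decreased-inclusion strain, `gdh1d`
as increased, and `taf11d` as an expression-confounded decoy (half
expression, hence fewer inclusions):

```r
library(inclusionscreen)

strains <- rbind(
  strain_spec("WT_his3", "HIS3",  true_inclusion_prob = 0.40),
  strain_spec("yke2d",   "YKE2",  true_inclusion_prob = 0.10),
  strain_spec("gdh1d",   "GDH1",  true_inclusion_prob = 0.65),
  strain_spec("taf11d",  "TAF11", true_inclusion_prob = 0.20,
              true_expression_scale = 0.5))

plate <- generate_plate_images(strains, imaging_config(noise_sd = 10),
                               replicates = 3, seed = 1)
res <- quantify_plate(plate$images, plate$platemap,
                      segmentation_params(min_cells_for_scoring = 30))
head(res$wells[, c("well", "strain_id", "n_cells", "pct_inclusion",
                   "diffuse_mean_cell_intensity", "qc_pass")], 4)
#>      well strain_id n_cells pct_inclusion diffuse_mean_cell_intensity qc_pass
#> 1 P01_A01   WT_his3      43         39.53                        1041    TRUE
#> 2 P01_A02   WT_his3      64         32.81                        1041    TRUE
#> 3 P01_A03   WT_his3      63         41.27                        1041    TRUE
#> 4 P01_A04     yke2d      43         11.63                        1040    TRUE

ph <- data.frame(strain_id = res$wells$strain_id,
                 replicate = res$wells$replicate,
                 pct_inclusion = res$wells$pct_inclusion,
                 mean_cell_intensity = res$wells$diffuse_mean_cell_intensity)
call_hits(ph, "WT_his3")
#>   strain_id              category p_inclusion p_intensity effect normalized_pct
#> 1     yke2d             decreased     0.00132    1.71e-01  -71.1           14.4
#> 2     gdh1d             increased     0.00416    6.65e-01   50.2           75.1
#> 3    taf11d expression_confounded     0.00932    2.57e-14  -41.8           29.1
```

Reading the output: `yke2d` wells average ~12% inclusion-carrying cells vs
~38% in WT — a 71% relative drop (`effect`), significant (`p_inclusion`),
with an unchanged expression control (`p_intensity = 0.17`), so it is a
`decreased` hit printing at 14.4 on the WT=50 scale. `taf11d` also loses
inclusions, but its intensity control collapses (`p_intensity ≈ 3e-14`), so
it is `expression_confounded`, not a hit.

Note the intensity column used: the whole-cell mean (the classical proxy)
is mechanically coupled to inclusion content, because bright puncta raise a
cell's mean — `diffuse_mean_cell_intensity` excludes punctum pixels and is
the cleaner expression readout. Both are reported; see the methods vignette.

Cytotoxicity from growth curves:

```r
g <- generate_growth_curves(rbind(
  strain_spec("WT_his3", "HIS3", construct = "dsRed_SY1",  true_generation_time_h = 2.7),
  strain_spec("WT_his3", "HIS3", construct = "dsRed_only", true_inclusion_prob = 0, true_generation_time_h = 2.5),
  strain_spec("yke2d",   "YKE2", construct = "dsRed_SY1",  true_generation_time_h = 3.3),
  strain_spec("yke2d",   "YKE2", construct = "dsRed_only", true_inclusion_prob = 0, true_generation_time_h = 2.5)),
  seed = 1)
gt <- generation_times(g$od, g$map)
toxicity_test(gt, "yke2d", "WT_his3")
#>   strain_id delta_g_mean delta_g_sd wt_delta_g_mean delta_delta_g        p significant
#> 1     yke2d        0.768     0.0849           0.181         0.587 0.000436        TRUE
```

Synphilin-1 expression costs `yke2d` an extra ~0.59 h of doubling time over
what it costs WT (planted: +0.6 h) — a synthetic-sick interaction.

## Command line

```sh
inclusion-screen run --config screen.toml          # full pipeline, summary.json
inclusion-screen quantify  --images DIR --platemap plate_map.csv --out OUT
inclusion-screen call-hits --wells OUT/wells.tsv --wt-strain WT_his3 --out hits.tsv
inclusion-screen enrich    --hits hits.txt --annotation ann.tsv --universe uni.txt --out enr.tsv
inclusion-screen network   --hits hits.txt --edges edges.tsv --out NETDIR
inclusion-screen growth    --od growth.csv --platemap map.csv --out GROWTH
```

The installed script lives at `exec/inclusion-screen`; a sample config is in
`inst/extdata/example_config.toml`.

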