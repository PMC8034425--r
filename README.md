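# screenkit

Analytics for small-molecule anticancer screening campaigns in the NCI60
style, written for computational chemists and translational bioinformaticians
who need the whole downstream arithmetic of such a campaign in one tested,
offline package: dose-response endpoint estimation, activity-fingerprint
comparison, target-prediction consensus, drug-likeness descriptors, tumor
genomics statistics, and interaction-network/gene-set summaries — plus
synthetic-data generators with known ground truth for every input class.

## What it computes

**Dose-response endpoints.** From time-zero (Tz), control (C) and treated
(Ti) plate signals, percent growth is the piecewise quantity

    PG = (Ti − Tz)/(C − Tz) × 100   if Ti ≥ Tz
    PG = (Ti − Tz)/Tz × 100         if Ti < Tz

and the three standard endpoint concentrations are where PG crosses 50
(GI50, 50% growth inhibition), 0 (TGI, total growth inhibition) and −50
(LC50, 50% net cell kill), found by linear interpolation of PG against
log10(concentration) and censored as `"> max"` / `"< min"` when the level
is not reached within the tested range.

**COMPARE fingerprints.** A compound's fingerprint is its vector of
per-cell-line potencies, −log10(endpoint in molar). A seed fingerprint is
ranked against a library by Pearson correlation over the common cell lines
(CCLC), with pairwise-complete missing-data handling and a minimum-overlap
guard.

**Drug-likeness.** From an MDL V2000 molfile the package derives molecular
weight, Lipinski H-bond donors (H on N/O) and acceptors (N + O count), Ertl
topological polar surface area from published fragment contributions,
fraction of sp3 carbons, rotatable bonds, and the Lipinski rule-of-five
verdict (logP and molar refractivity consumed as external inputs).

**Tumor genomics.** Alteration frequencies, co-occurrence enrichment versus
an index gene (per-gene 2×2 Fisher tests, Benjamini–Hochberg q-values, and
log2 ratios of group percentages as printed in clinical-portal tables),
Wilcoxon expression comparisons, median-split grouping, Kaplan–Meier
curves, and the Mantel–Cox log-rank test with an O/E hazard ratio and
log-scale 95% CI.

**Networks and gene sets.** PPI-graph summaries (nodes, edges, average
degree 2E/N, average local clustering), hub identification, and
hypergeometric gene-set enrichment with the p < 10⁻⁵ / count ≥ 3 /
strength ≥ 2 filtering rule, where strength = log10(observed/expected
overlap).

## Worked example

```r
library(screenkit)

# drug-likeness of the packaged study compound
mol <- read_molfile(system.file("extdata", "nsc765598.mol", package = "screenkit"))
descriptor_set(mol, logp = 4.867901, molar_refractivity = 87.77)
#>       formula     mw n_hbd n_hba  tpsa frac_csp3 n_rotatable lipinski_pass
#> 1 C19H11F4NO2 361.29     2     3 49.33         0           4          TRUE
```

The molecule weighs 361.29 g/mol, presents 2 H-bond donors (phenolic O–H,
amide N–H) and 3 Lipinski acceptors (1 N + 2 O; the four fluorines do not
count), has a polar surface area of 49.33 Å² (20.23 + 17.07 + 12.03 from
the hydroxyl, carbonyl and amide fragments), no sp3 carbon, 4 rotatable
bonds, and passes every rule-of-five criterion.

```r
# a synthetic nine-line screen and its endpoint summary
gp <- gen_dose_plates(n_lines = 9, seed = 7)
s  <- summarize_screen(gp$plates)
head(s$params[, c("cell_line", "panel", "gi50_label", "tgi_label", "lc50_label")], 5)
#>   cell_line    panel gi50_label tgi_label lc50_label
#> 1   SYN-001    NSCLC          4        26      > 100
#> 2   SYN-002 Leukemia        1.8        29      > 100
#> 3   SYN-003 Melanoma        1.2       9.7      > 100
#> 4   SYN-004    Renal        1.3       3.1        7.4
#> 5   SYN-005    Colon        1.4        19      > 100
```

Endpoints are reported in µM; cell lines whose growth never fell to the
LC50 level are censored at the highest tested concentration (`> 100`).
The whole pipeline runs end to end from one configuration:

```r
bundle <- run_pipeline(default_pipeline_config(out_dir = "run1", seed = 1))
cat(render_report(bundle), sep = "\n")
```

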