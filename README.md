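# glycoSecretome

Label-free profiling of cancer cell-line **secretomes** and
**N-glycosecretomes** across a metastatic gradient, as an installable,
tested R pipeline. The motivating setting is a panel of hepatocellular
carcinoma (HCC) lines ordered by metastatic potential —
Hep3B < MHCC97L < MHCC97H < HCCLM3 — profiled by LC-MS/MS from serum-free
conditioned medium: which secreted gene products rise monotonically with
metastatic potential, which of their N-glycosites rise with them, and do
the two arms agree on a candidate biomarker set?

The package is for proteomics bioinformaticians who want the complete
analysis chain behind such a study as reusable, seedable components:

* **PSM quality control** — target-decoy peptide q-values (monotonized
  running FDR, decoys-first at ties) and a stepwise stringent filter
  (ion score > 30 with q < 1%, *or* score > 40 with q < 5%; minimum
  peptide length 7).
* **Parsimony protein inference** — exact substring peptide mapping,
  merge/subsume/greedy-set-cover grouping, gene-product (GP) collapsing,
  and unique-peptide quantifiability.
* **Spectral-count quantification** — for each GP and run,
  `SAF1 = 10 * PSMs / theoretical tryptic peptides` and
  `NSAF5 = 1e5 * SAF1 / total SAF1` (every run column sums to 1e5), with
  replicate Pearson correlations and a one-way ANOVA screen (p < 0.05,
  uncorrected).
* **Trend clustering** — k-means on z-scored per-line means (k = 3
  secretome, k = 2 glyco); a cluster is *increased* only if its centroid
  is strictly monotone over the metastatic ranks.
* **N-glycosite validation and quantification** — a deamidated peptide is
  a site only if the flagged N maps to a canonical sequon N-X(≠P)-[S/T]
  and the mass delta matches n × 2.9848 Da within n × 0.01 Da (the 18O
  deglycosylation mark); accepted sites are quantified as precursor-area
  shares of the run total.
* **Secretion categorization** — SignalP/SecretomeP/TMHMM predictor
  outputs → classical secretome (Part4), extracellular membrane (Part3),
  non-classical secretome (Part1), other (Part2).
* **Clinical statistics** — Pearson chi-square with and without Yates
  correction and Fisher's exact test for 2×k marker-by-covariate tables,
  including the packaged 75-patient DKK3 contingency tables.
* **Synthetic data with planted truth** — every input above can be
  simulated (Poisson PSM counts, log-normal areas, decoys, sequon-true
  glycosites, class-consistent predictor scores, null or associated
  clinical cohorts), so the whole pipeline is validated by parameter
  recovery.

## Worked example

```r
library(glycoSecretome)

run <- runPipeline(pipelineConfig(seed = 1, nProteins = 300))
run
#> SecretomeRun (seed 1)
#>   PSMs: 76661 -> 66377 after QC
#>   groups: 300 | GPs: 300 | quantifiable: 300
#>   ANOVA significant: 109 | secretome increased: 32
#>   glycosites accepted: 3320 rejected: 380 | glyco increased GPs: 25
#>   candidates: 25
head(candidates(run))
#> [1] "GENE00003" "GENE00017" "GENE00043" "GENE00057" "GENE00059" "GENE00083"
```

Reading the report: 76,661 simulated PSMs (including decoys) enter; the
stepwise filter keeps 66,377 targets; parsimony grouping and gene collapse
yield 300 quantifiable GPs; 109 differ across the four lines at p < 0.05;
the strictly-monotone-up k-means cluster holds 32 GPs. In the glyco arm,
3,320 site records pass sequon + mass-shift validation (380 contaminant
records are rejected), and 25 GPs carry sites in the increasing cluster.
The intersection of the two increased sets — 25 candidate GPs — recovers
100% of the GPs planted as increased in both arms at this seed.

The clinical module reproduces the published DKK3 association table from
its printed counts:

```r
clinicalAssociation()
#>                variable variant          p published_p
#> 1                   sex   yates 0.18482805       0.185
#> 2                   age pearson 0.85271715       0.853
#> 3    maximal_tumor_size pearson 0.06049689       0.060
#> 4       liver_cirrhosis pearson 0.53444401       0.534
#> 5       venous_invasion   yates 0.21719463       0.217
#> 6 tumor_differentiation pearson 0.64538697       0.645
```

A thin CLI over the same functions lives in
`inst/scripts/secretome-pipeline.R`
(`all | simulate | qc | clinical` subcommands); all stage artifacts are
plain TSV/JSON.

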