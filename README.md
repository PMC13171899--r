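# starpgx

Star-allele pharmacogenetic interpretation of whole-genome cohorts.

Whole-genome sequencing performed for rare-disease diagnostics can be
reused, at essentially no extra cost, for pharmacogenetic (PGx)
interpretation: nearly every individual carries at least one genotype for
which a published CPIC or DPWG guideline recommends a therapy adjustment.
`starpgx` implements that interpretation pipeline end to end for the twelve
guideline genes *CYP2B6, CYP2C19, CYP2C9, CYP2D6, CYP3A5, DPYD, G6PD,
NUDT15, TPMT, SLCO1B1, VKORC1* and *ABCG2*:

* **Diplotype calling** — per gene, the star-allele pair
  (e.g. CYP2C19\*1/\*2) whose defining variants best explain the observed
  genotypes, with a deterministic tie-break and an explicit indeterminate
  state for unexplained calls.
* **Phenotype translation** — metabolizer phenotypes (UM/RM/NM/IM/PM) from
  allele function pairs or activity-score sums (CYP2D6, CYP2C9: the
  diplotype activity score Σ AS binned at CPIC-style thresholds),
  transporter function for SLCO1B1, X-linked handling for G6PD, tag-variant
  genotypes for VKORC1/ABCG2, plus an actionable-variant flag.
* **Overlays** — exon-level CNV calls (filtered to >2 exons with split-read
  support) and rare high-impact variants (frameshift/stop/splice at
  population AF < 1 %) revise called phenotypes; each revision is classified
  as no change, phenotype-only, phenotype-and-recommendation, potential, or
  not interpretable.
* **Gene-drug pairs (GDPs)** — medication records joined with phenotypes
  per implicated gene and classified against a bundled guideline
  recommendation table (categories: no action, dosing, alternate drug,
  dosing/alternate drug, other), with cohort-level aggregation.
* **Synthetic cohorts** — a pedigree-aware simulator (families, Mendelian
  star-allele inheritance, CNV/LoF injection, medication sampling) with
  full ground truth, emitting VCF + CNV TSV + medications CSV + PED.

## Worked example

Call a diplotype from variant records, translate it, and build gene-drug
pairs:

```r
library(starpgx)
defs <- load_allele_definitions()   # bundled star-allele knowledge base
gl   <- load_guideline_table()      # bundled recommendation table

# one individual, heterozygous for the CYP2C19*2 defining variant
v    <- defs$variants[defs$variants$gene == "CYP2C19" &
                      defs$variants$allele == "*2", ]
vars <- variant_records(v$chrom, v$pos, v$ref, v$alt, dosage = 1L)
dip  <- call_diplotype(vars, "CYP2C19", defs)
dip
#> <pgx_diplotype> CYP2C19 *1/*2

assign_phenotype(dip, defs, guideline = gl)
#>      gene allele_1 allele_2 phenotype activity_score guideline_label actionable_variant
#> 1 CYP2C19       *1       *2        IM             NA              IM               TRUE

meds <- tibble::tibble(individual_id = "P01",
                       drug = c("pantoprazole", "clopidogrel"))
phen <- tibble::tibble(individual_id = "P01", gene = "CYP2C19",
                       guideline_label = "IM")
build_gdps(meds, phen, gl)
#>   individual_id         drug    gene phenotype recommendation actionable
#> 1           P01 pantoprazole CYP2C19        IM         dosing       TRUE
#> 2           P01  clopidogrel CYP2C19        IM alternate_drug       TRUE
```

The individual is a CYP2C19 intermediate metabolizer; both prescribed
drugs carry a guideline recommendation for that phenotype (a dosing
strategy for pantoprazole, an alternative drug for clopidogrel), so both
gene-drug pairs are actionable.

For a full synthetic run:

```r
sim <- simulate_cohort(cohort_config(n_families = 50, seed = 1))
res <- run_pipeline(sim$files$vcf, sim$files$cnv, sim$files$medications,
                    sim$files$ped, out_dir = "pgx_out")
res$summary$gdp_count           # total gene-drug pairs
res$summary$actionable_gdp_count
```

A thin command-line wrapper with `simulate`, `interpret` and `fixtures`
subcommands ships at `inst/cli/starpgx.R`.

## Package layout

* `R/` — knowledge-base loaders, diplotype caller, phenotype translation,
  overlay engine, GDP actionability, cohort simulator, pipeline driver.
* `inst/extdata/` — allele definitions, guideline recommendation table,
  incidence-count table (all versioned TSV).
* `vignettes/interpretation-methods.Rmd` — models, thresholds, design
  decisions and limitations.
* `tests/testthat/` — unit, property and reproduction tests.
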