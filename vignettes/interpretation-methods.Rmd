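---
title: "Methods: star-allele interpretation, overlays and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: star-allele interpretation, overlays and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starpgx)
```

# Scope and model

`starpgx` implements a pharmacogenetic (PGx) interpretation pipeline for
whole-genome small-variant calls: per-gene star-allele diplotype calling,
diplotype-to-phenotype translation, structural-variant and rare-variant
phenotype overlays, and gene-drug-pair (GDP) actionability classification
against a CPIC/DPWG-style recommendation table. Twelve genes with published
prescribing guidelines are interpreted (CYP2B6, CYP2C19, CYP2C9, CYP2D6,
CYP3A5, DPYD, G6PD, NUDT15, TPMT, SLCO1B1, VKORC1, ABCG2); COMT is carried
through the structural-variant overlay only, as it has no guideline.

All knowledge is data, not code: star-allele definitions (defining
variants, function labels, activity values) and the guideline
recommendation table ship as versioned TSV fixtures under `extdata/` and
are validated on load. There is no live access to online guideline
resources, so results are reproducible against a fixed knowledge snapshot.

# Diplotype calling

The caller is a deliberately simple matcher, not a combinatorial haplotype
model: read-backed phasing, hybrid alleles and novel-allele discovery are
out of scope. For a gene with alleles $a_1, \dots, a_k$ (each a set of
defining variants), every unordered pair is scored against the observed
alternate-allele dosages at defining positions. A pair is *feasible* if it
never predicts more alternate alleles than observed, and its score is the
number of observed non-reference defining genotypes it explains exactly.
Ties break deterministically: fewer non-reference alleles first (the
"default to the reference allele" convention), then the smallest star
numbers. If the best pair still leaves an observed defining genotype
unexplained the call is flagged and the phenotype becomes `indeterminate`
rather than an error. Sub-allele suffixes (`*2B`) normalize to their core
allele (`*2`) for function lookup while the suffix is retained for display.

Because the definition tables bundled here use non-overlapping defining
variants for nearly all alleles, the matcher recovers simulated truth
exactly; the test suite verifies equivalence with a brute-force all-pairs
oracle on randomly generated toy tables, including overlapping-definition
cases.

# Phenotype translation

Four vocabularies are used:

* **Function pairs** (CYP2B6, CYP2C19, CYP3A5, DPYD, NUDT15, TPMT): the two
  allele function labels map through a fixed lookup — two no/decreased
  alleles give PM, one gives IM, two normals NM, normal+increased RM, two
  increased UM. Genes without a described increased-function allele span
  only NM/IM/PM.
* **Activity scores** (CYP2D6, CYP2C9): per-allele activity values are
  summed and binned. Defaults follow CPIC-style thresholds (CYP2D6: PM = 0,
  IM (0, 1.25), NM [1.25, 2.25], UM > 2.25; CYP2C9: PM at or below 0.5, IM
  (0.5, 1.5], NM = 2). The thresholds in force at any given guideline
  version are an assumption; they are exposed via `activity_bins()` and can
  be overridden. CYP2C9 IM calls retain their score because guidance
  differs between activity 1.5 and 1.0 — the guideline lookup key splits
  them (`IM (AS 1.5)` vs `IM (AS 1)`).
* **Transporter function** (SLCO1B1): increased / normal / decreased / poor
  function.
* **Tag-variant genotypes** (VKORC1 rs9923231, ABCG2 rs2231142) and
  **G6PD** (normal / variable / deficient, X-linked: hemizygous or
  homozygous deficient alleles give "deficient", heterozygous females
  "variable").

An *actionable variant* is a phenotype for which at least one guideline
entry recommends a therapy adjustment. The default policy excludes
normal/wildtype phenotypes; an `include_normal` policy exists because a few
drugs (pantoprazole, atomoxetine) carry recommendations even for normal
metabolizers, which changes the population fraction flagged substantially
(CYP2C19 becomes actionable for everyone).

# Structural-variant and rare-variant overlays

CNV calls enter as exon-level segments and are filtered before
interpretation: a call is retained only if it spans **three or more exons**
("larger than two exons" is read as a strict inequality; the two-exon
boundary case is tested) *and* has split-read support. Both criteria are
false-positive controls for depth-based CNV calling.

**Deletions** replace one allele with a no-function allele. Partial
deletions that remove exon 1 or truncate the reading frame are treated like
whole-gene deletions — the reasoning applied to the CYP2C19 exon 1–5 and
CYP3A5 exon 5–7 events. The deleted allele's identity is never guessed: a
heterozygous prior yields one candidate per choice, a homozygous prior a
single deterministic candidate. Deletion candidates can never rank above
the prior phenotype (tested as a monotonicity property).

**Duplications** use a three-copy scoring model separate from the two-copy
engine: per-allele function scores (activity values where defined,
otherwise no = 0, decreased = 0.5, normal = 1, increased = 1.5) are summed
over the two original alleles plus the duplicated copy and binned at
PM ≤ 0.5 < IM ≤ 1.5 < NM ≤ 2.25 < RM ≤ 3.0 < UM. The thresholds are chosen
so that an extra normal copy on a normal diplotype gives RM (three normal
copies, total 3.0), while an extra copy of a decreased allele compensates an
IM to NM (e.g. a *6 duplication on CYP2B6 *1/*6 totals 2.0). A duplicated
copy of the *normal* allele in the same diplotype totals 2.5 and lands on
RM, so the candidate set for CYP2B6 *1/*6 is {NM, RM} — the ambiguity is
carried, not resolved. Revised labels may fall outside the set of described
two-copy diplotypes (a CYP2C9 duplication of *1/*1 gives RM, which no
guideline row covers); such labels cannot produce a *definite*
recommendation change.

**Rare variants** are retained when they classify as HIGH impact
(frameshift, stop-gained, start-lost, splice-site within 2 nt of an exon
boundary), have a general-population allele frequency below 1 % (absent
annotations are treated as rare), and are not defining variants of a known
star allele — the latter are the diplotype caller's remit. The consequence
classifier runs over toy transcript models (one synthetic contig per gene,
150 bp exons, 100 bp introns, a stop-free repeating CDS); real transcript
models are pluggable through the same structure. A retained
loss-of-function variant is assigned to each allele in turn, converting its
function to no-function, exactly like a deletion.

Each overlay yields a **change class** computed by comparing guideline
recommendations between the prior phenotype and every candidate across all
drugs covered for the gene (not only prescribed drugs, since a phenotype
change matters "for at least one drug"): `none` when every candidate equals
the prior; `phenotype_only` / `phenotype_and_recommendation` when the
candidates agree on a single new label; `potential` when candidates
disagree (or the prior call itself was ambiguous) and at least one
candidate changes a recommendation; `not_interpretable` for genes without
guideline coverage (COMT) or unknown priors. Candidate sets that disagree
without any recommendation consequence fall back to `phenotype_only`.

# Gene-drug pairs and cohort aggregation

Medication records are deduplicated per (individual, canonical drug) —
exposure means "took the drug at least once", with the record source kept
for provenance only. Drug names normalize to lowercase through a synonym
map (paracetamol/acetaminophen; citalopram and escitalopram share one
guideline key; common spelling variants). Each covered drug then yields one
GDP per implicated gene; a drug can implicate several genes (amitriptyline
pairs with both CYP2C19 and CYP2D6). Actionable categories are dosing,
alternate drug, their combination, and "other" entries individually marked
actionable in the fixture. Uncovered drugs and missing phenotype calls are
reported, never silently dropped. Combined two-gene recommendations are out
of scope; drugs with more than one implicated gene are visible in the GDP
table for downstream combination.

Two fixture decisions in the bundled recommendation table deserve note.
The clopidogrel/CYP2C19 IM entry is encoded as `alternate_drug`
(actionable): the per-row label in the printed table the fixture was
transcribed from appears garbled, but that table's per-drug actionable
count (1 of 3) and standard CPIC guidance for IMs under clopidogrel both
require an actionable IM entry. "Other" entries default to non-actionable
unless the printed actionable counts require otherwise (tramadol/CYP2D6/IM
is the single actionable "other").

Carrier frequencies of structural and rare events are reported under two
conventions, labelled explicitly: carriers per individuals (the convention
the source tables print as "AF": 7 carriers in 1000 is 0.7 %) and variant
alleles per total alleles (0.35 % for the same event, assuming heterozygous
carriers).

# Synthetic cohorts

The simulator emulates the statistical structure the analysis assumes: a
rare-disease cohort of families (default 389 families with a size
distribution averaging about 2.57, targeting roughly 1000 individuals),
founder star-alleles drawn independently per gene from configured
frequencies, Mendelian inheritance for offspring (one allele per available
parent; missing parents are population draws), X-linked handling for G6PD,
structural and loss-of-function events at configured per-individual carrier
frequencies (the CYP2C19 exon 1–5 deletion at 0.7 %, the remaining events
at 0.1–0.6 %), and medication sampling for a 35.9 % subcohort using printed
drug prevalences (ibuprofen 22.0 %, pantoprazole 21.5 %, acetaminophen
17.6 %) plus a Poisson count of non-guideline drugs. Per-gene allele
frequencies are not part of the bundled knowledge snapshot; the defaults in
`default_allele_frequencies()` are plausible European-like values chosen
once and documented here — they are deliberately excluded from any exact
reproduction target. Under these defaults more than 90 % of simulated
individuals carry at least one actionable variant, in line with the
~97 % prevalence reported for comparable European cohorts.

Features of real data the simulator does **not** model: linkage
disequilibrium within and between genes, population structure and
ethnicity strata, CNV/LoF transmission within families (events are placed
on random carriers, not inherited), phasing, and correlated polypharmacy
(drugs are sampled independently, so per-individual GDP counts run lower
than in a real chronically-ill cohort). Passing recovery tests on synthetic
cohorts therefore demonstrates internal consistency of caller and emitter,
not calling accuracy on sequencing data.

Everything is seed-deterministic: a fixed seed reproduces the truth tables
and emitted files byte for byte (VCF via `vcfR`, CNV segments as BED-like
TSV, medications CSV, PED).

# Numerical and engineering choices

* Problem sizes: unit and property tests simulate 15–80 families and use
  25–40 random toy definition tables; the acceptance script simulates the
  full 389-family cohort once. These sizes give stable statistics while
  keeping the default test run to a couple of minutes.
* Unknown drug/gene lookups return an explicit not-covered signal (`NULL`),
  never a default; a covered drug queried with an unknown phenotype label
  is an error in strict mode because it indicates a data bug.
* `indeterminate` phenotypes resolve to a synthesized no-action entry and
  are never actionable.
* Degenerate inputs: an empty variant set calls the reference diplotype; an
  empty medication table yields zero GDPs with zeroed summaries; conflicting
  duplicate genotype records at one position are an input error.
* Mean/SD of per-individual GDP counts are computed over individuals with
  at least one pair (matching the "x GDPs across y individuals"
  convention); sample SD is the default with a population-SD switch.

# Known limitations

CYP2D6 structural alleles (gene deletions, duplications, hybrids) are not
resolved: CYP2D6 CNV nomenclature is the province of dedicated star-allele
callers, and the overlay engine here deliberately addresses CNVs in the
*other* pharmacogenes, where no such caller support exists. The
consequence classifier is a simplified stand-in for a full
annotation engine and covers frameshift, stop-gained, start-lost and
splice-site classes only. The second stop-gained carrier in the bundled
replay fixture has an unstated prior diplotype and is deliberately
excluded from definite-change counting (`not_interpretable`).
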