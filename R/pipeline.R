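#' Read a multi-sample VCF of small-variant calls
#'
#' Wraps `vcfR::read.vcfR`; keeps PASS (or missing-filter) biallelic
#' records, parses per-sample genotypes into alternate-allele dosages and
#' pulls population AF annotations from INFO/AF.
#'
#' @param path VCF path (plain or bgzipped).
#' @param pass_only drop records whose FILTER is neither PASS nor ".".
#' @return list: `sites` tibble (chrom, pos, ref, alt, population_af),
#'   `dosage` integer matrix (sites x samples), `samples`.
#' @export
read_vcf_variants <- function(path, pass_only = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- rep(TRUE, nrow(fix))
  if (pass_only)
    keep <- fix[, "FILTER"] %in% c("PASS", ".", NA)
  af <- suppressWarnings(vcfR::extract.info(v, "AF", as.numeric = TRUE))
  gt <- vcfR::extract.gt(v, "GT")
  sites <- tibble::tibble(chrom = fix[keep, "CHROM"],
                          pos = as.integer(fix[keep, "POS"]),
                          ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                          population_af = af[keep])
  gtk <- gt[keep, , drop = FALSE]
  dosage <- apply(gtk, 2, function(col) {
    vapply(strsplit(ifelse(is.na(col), "0", col), "[/|]"), function(x)
      sum(x == "1"), integer(1))
  })
  dosage <- matrix(as.integer(dosage), nrow = nrow(sites),
                   dimnames = list(NULL, colnames(gtk)))
  list(sites = sites, dosage = dosage, samples = colnames(gtk))
}

#' @rdname read_vcf_variants
#' @param vcfdata list from [read_vcf_variants()].
#' @param id sample identifier.
#' @export
individual_variants <- function(vcfdata, id) {
  j <- match(id, vcfdata$samples)
  if (is.na(j)) stop("sample not in VCF: ", id, call. = FALSE)
  s <- vcfdata$sites
  s$dosage <- vcfdata$dosage[, j]
  s[s$dosage > 0, , drop = FALSE]
}

#' Read a PED pedigree file
#'
#' @param path whitespace-separated PED (family, individual, father, mother,
#'   sex, phenotype), no header.
#' @return tibble with "0" parent codes converted to NA and sex as M/F.
#' @export
read_ped <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("family_id", "individual_id",
                                       "father_id", "mother_id", "sex",
                                       "phenotype"))
  p$father_id[p$father_id == "0"] <- NA_character_
  p$mother_id[p$mother_id == "0"] <- NA_character_
  p$sex <- ifelse(p$sex == 1, "M", ifelse(p$sex == 2, "F", NA))
  tibble::as_tibble(p)
}

#' Call diplotypes and phenotypes for every individual and gene
#'
#' @param vcfdata list from [read_vcf_variants()].
#' @param defs allele definitions.
#' @param guideline guideline table (for actionable-variant flags).
#' @param sex named character vector (M/F) per sample; individuals missing
#'   from it are treated as female for X-linked calling.
#' @param policy actionable-phenotype policy.
#' @return list: `phenotypes` tibble (one row per individual x gene) and
#'   `diplotypes` (nested list keyed `id` then `gene`).
#' @export
call_cohort_phenotypes <- function(vcfdata, defs, guideline = NULL,
                                   sex = NULL, policy = "default") {
  genes <- intersect(pgx_genes()$gene, unique(defs$alleles$gene))
  xg <- pgx_genes()$gene[pgx_genes()$x_linked]
  rows <- list()
  dips <- list()
  for (id in vcfdata$samples) {
    vars <- individual_variants(vcfdata, id)
    dips[[id]] <- list()
    for (g in genes) {
      hemi <- g %in% xg && !is.null(sex) && identical(unname(sex[id]), "M")
      gv <- vars[vars$chrom == g, , drop = FALSE]
      dip <- call_diplotype(gv, g, defs, hemizygous = hemi)
      ph <- assign_phenotype(dip, defs, guideline = guideline,
                             policy = policy)
      ph$individual_id <- id
      ph$unexplained <- dip$unexplained
      rows[[length(rows) + 1]] <- ph
      dips[[id]][[g]] <- dip
    }
  }
  phen <- dplyr::bind_rows(rows)
  phen <- phen[, c("individual_id", setdiff(names(phen), "individual_id"))]
  list(phenotypes = phen, diplotypes = dips)
}

#' Run the full interpretation pipeline
#'
#' Knowledge loading, diplotype/phenotype calling, CNV and rare-variant
#' overlays, gene-drug-pair construction, and cohort aggregation, with a
#' report bundle written to `out_dir`: `phenotypes.tsv`, `overlays.tsv`,
#' `gdps.tsv`, `incidence_cells.tsv` and `summary.json`.
#'
#' @param vcf path to the multi-sample VCF.
#' @param cnv path to the CNV segment TSV (may be NULL).
#' @param medications path to the medications CSV (may be NULL).
#' @param ped path to the PED file (may be NULL; then all individuals are
#'   treated as unrelated females for X-linked calling).
#' @param out_dir output directory.
#' @param defs,guideline knowledge bases.
#' @param policy actionable-phenotype policy ("default" or
#'   "include_normal").
#' @param unrelated_only keep one individual per family (the index, i.e.
#'   the family's first offspring, or its first member).
#' @return list with `phenotypes`, `overlays`, `gdps`, `summary`, `files`
#'   (invisibly).
#' @export
run_pipeline <- function(vcf, cnv = NULL, medications = NULL, ped = NULL,
                         out_dir = tempfile("pgxrun"),
                         defs = load_allele_definitions(),
                         guideline = load_guideline_table(),
                         policy = "default", unrelated_only = FALSE) {
  for (p in c(vcf, cnv, medications, ped))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vcfdata <- read_vcf_variants(vcf)
  pedigree <- if (!is.null(ped)) read_ped(ped) else NULL
  sex <- if (!is.null(pedigree))
    stats::setNames(pedigree$sex, pedigree$individual_id) else NULL

  samples <- vcfdata$samples
  if (unrelated_only && !is.null(pedigree)) {
    keep <- vapply(split(pedigree, pedigree$family_id), function(fam) {
      child <- fam$individual_id[!is.na(fam$father_id) |
                                 !is.na(fam$mother_id)]
      if (length(child)) child[1] else fam$individual_id[1]
    }, character(1))
    samples <- intersect(samples, keep)
    vcfdata$samples <- samples
    vcfdata$dosage <- vcfdata$dosage[, samples, drop = FALSE]
  }

  called <- call_cohort_phenotypes(vcfdata, defs, guideline, sex, policy)
  phen <- called$phenotypes

  # CNV overlays
  overlays <- list()
  if (!is.null(cnv)) {
    calls <- read_cnv_calls(cnv)
    calls <- calls[calls$individual_id %in% samples, , drop = FALSE]
    kept <- filter_cnv_calls(calls)
    if (nrow(calls) > nrow(kept))
      message(nrow(calls) - nrow(kept),
              " CNV call(s) removed by size/split-read filter")
    for (i in seq_len(nrow(kept))) {
      cc <- kept[i, ]
      prior <- list(diplotype = called$diplotypes[[cc$individual_id]][[cc$gene]],
                    phenotype = phen[phen$individual_id == cc$individual_id &
                                     phen$gene == cc$gene, ])
      if (is.null(prior$diplotype)) next
      res <- if (cc$kind == "deletion")
        apply_deletion_overlay(prior, cc, defs, guideline)
      else apply_duplication_overlay(prior, cc, defs, guideline)
      res$individual_id <- cc$individual_id
      overlays[[length(overlays) + 1]] <- res
    }
  }

  # rare-variant overlays
  for (id in samples) {
    vars <- individual_variants(vcfdata, id)
    rare <- filter_rare_high_impact(vars, defs)
    for (i in seq_len(nrow(rare))) {
      rr <- rare[i, ]
      if (!rr$gene %in% names(called$diplotypes[[id]])) next
      prior <- list(diplotype = called$diplotypes[[id]][[rr$gene]],
                    phenotype = phen[phen$individual_id == id &
                                     phen$gene == rr$gene, ])
      res <- apply_lof_overlay(prior, rr, defs, guideline)
      res$individual_id <- id
      overlays[[length(overlays) + 1]] <- res
    }
  }
  overlays <- if (length(overlays)) dplyr::bind_rows(overlays) else
    tibble::tibble(gene = character(0), kind = character(0),
                   prior = character(0), candidates = character(0),
                   n_candidates = integer(0), phenotype_modified = logical(0),
                   change_class = character(0), individual_id = character(0))

  # gene-drug pairs
  guideline_phen <- phen[phen$gene %in% guideline_genes(), ]
  meds <- NULL
  gdps <- NULL
  if (!is.null(medications)) {
    meds <- read_medications(medications)
    meds <- meds[meds$individual_id %in% samples, , drop = FALSE]
    gdps <- build_gdps(meds, guideline_phen, guideline)
    if (length(attr(gdps, "uncovered_drugs")))
      message(length(attr(gdps, "uncovered_drugs")),
              " drug(s) without guideline coverage produced no pairs")
  } else {
    gdps <- build_gdps(tibble::tibble(individual_id = character(0),
                                      drug = character(0)),
                       guideline_phen, guideline)
  }

  summary <- summarize_cohort(
    gdps, phenotypes = guideline_phen,
    n_individuals = length(samples),
    n_with_medication_data = if (!is.null(meds))
      length(unique(meds$individual_id)) else 0L)
  t1 <- reconstruct_incidence_table(gdps)

  files <- list(
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    overlays = file.path(out_dir, "overlays.tsv"),
    gdps = file.path(out_dir, "gdps.tsv"),
    incidence_cells = file.path(out_dir, "incidence_cells.tsv"),
    summary = file.path(out_dir, "summary.json"))
  utils::write.table(phen, files$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(overlays, files$overlays, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gdps, files$gdps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(t1$cells, files$incidence_cells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_summary <- summary
  json_summary$by_gene <- NULL
  json_summary$by_drug <- NULL
  jsonlite::write_json(json_summary, files$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  invisible(list(phenotypes = phen, overlays = overlays, gdps = gdps,
                 summary = summary, incidence_table = t1, files = files))
}
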