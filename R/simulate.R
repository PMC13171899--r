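#' Default star-allele frequencies
#'
#' Plausible European-like per-gene star-allele frequencies used by the
#' cohort simulator. The study does not publish its frequency inputs; these
#' defaults are documented assumptions (methods vignette) and are not part
#' of any reproduction target.
#'
#' @return named list: gene -> named numeric vector summing to 1.
#' @export
default_allele_frequencies <- function() {
  list(
    CYP2B6  = c("*1" = 0.72, "*6" = 0.25, "*4" = 0.03),
    CYP2C19 = c("*1" = 0.63, "*2" = 0.14, "*3" = 0.01, "*17" = 0.22),
    CYP2C9  = c("*1" = 0.79, "*2" = 0.13, "*3" = 0.08),
    CYP2D6  = c("*1" = 0.40, "*2" = 0.28, "*4" = 0.20, "*10" = 0.03,
                "*41" = 0.09),
    CYP3A5  = c("*1" = 0.07, "*3" = 0.92, "*6" = 0.01),
    DPYD    = c("*1" = 0.97, "*2A" = 0.01, "HapB3" = 0.02),
    G6PD    = c("B" = 0.96, "A-" = 0.03, "Mediterranean" = 0.01),
    NUDT15  = c("*1" = 0.96, "*3" = 0.04),
    TPMT    = c("*1" = 0.95, "*3A" = 0.04, "*3C" = 0.01),
    SLCO1B1 = c("*1" = 0.80, "*5" = 0.15, "*14" = 0.05),
    VKORC1  = c("wildtype" = 0.61, "rs9923231" = 0.39),
    ABCG2   = c("wildtype" = 0.89, "rs2231142" = 0.11),
    COMT    = c("Val" = 0.50, "Met" = 0.50)
  )
}

#' Default structural and rare-variant event models
#'
#' Carrier frequencies follow the event spectrum observed in the study
#' cohort (e.g. the CYP2C19 exon 1-5 deletion at 7 carriers per 1000).
#'
#' @return tibble of events with per-individual carrier frequencies.
#' @export
default_cnv_events <- function() {
  tibble::tibble(
    gene = c("CYP2C19", "COMT", "CYP3A5", "COMT", "CYP2B6", "CYP2C9"),
    kind = c("deletion", "deletion", "deletion", "duplication",
             "duplication", "duplication"),
    exon_start = c(1L, 1L, 5L, 1L, 1L, 1L),
    exon_end = c(5L, 6L, 7L, 6L, 9L, 9L),
    carrier_frequency = c(0.007, 0.003, 0.002, 0.003, 0.001, 0.001))
}

#' @rdname default_cnv_events
#' @export
default_lof_events <- function() {
  tibble::tibble(
    gene = c("CYP3A5", "CYP3A5", "CYP3A5", "CYP2C19", "SLCO1B1"),
    lof_type = c("frameshift_dup", "frameshift_del", "stop_gained",
                 "stop_gained", "frameshift_del"),
    lof_cds = c(247L, 1372L, 746L, 463L, 1925L),
    carrier_frequency = c(0.002, 0.006, 0.002, 0.001, 0.001))
}

#' Default medication-sampling model
#'
#' Per-drug exposure probabilities follow the printed prevalences of the
#' study subcohort (ibuprofen 22.0%, pantoprazole 21.5%, acetaminophen
#' 17.6%, remaining guideline drugs at their reported pair counts / 359);
#' non-guideline prescriptions are modelled as a Poisson count of dummy
#' drugs so that medicated individuals average roughly 5.4 drugs.
#'
#' @return list with `drug_probs` (named numeric) and
#'   `mean_nonguideline` (Poisson mean for drugs without guidelines).
#' @export
default_medication_model <- function() {
  n_sub <- 359
  counts <- c(
    ibuprofen = 79, pantoprazole = 77, acetaminophen = 63, risperidone = 24,
    metoprolol = 20, omeprazole = 16, sertraline = 13, atorvastatin = 13,
    ondansetron = 13, amitriptyline = 10, "(es)citalopram" = 10, tramadol = 8,
    simvastatin = 8, celecoxib = 6, aripiprazole = 6, venlafaxine = 5,
    mercaptopurine = 5, allopurinol = 4, flecainide = 4, trimipramine = 4,
    tacrolimus = 4, rosuvastatin = 3, atomoxetine = 3, haloperidol = 3,
    azathioprine = 3, thioguanine = 3, clopidogrel = 3, doxepin = 2,
    tamoxifen = 2, dapsone = 2, voriconazole = 2, phenytoin = 1,
    lovastatin = 1, pravastatin = 1, propafenone = 1, zuclopenthixol = 1,
    nitrofurantoin = 1, phenprocoumon = 1, fluorouracil = 1)
  list(drug_probs = counts / n_sub, mean_nonguideline = 3)
}

#' Cohort simulation configuration
#'
#' @param n_families number of families.
#' @param family_size_probs named numeric: probability of family sizes
#'   (names are sizes). The default targets the study's 389 families /
#'   1000 individuals (mean size about 2.57).
#' @param allele_frequencies per-gene star-allele frequencies (each must
#'   sum to 1).
#' @param cnv_events,lof_events event tibbles (see [default_cnv_events()]).
#' @param medication_model see [default_medication_model()].
#' @param fraction_with_medication_data fraction of individuals whose drug
#'   history is available (study: 35.9%).
#' @param seed integer RNG seed.
#' @return validated `pgx_cohort_config` list.
#' @export
cohort_config <- function(n_families = 389,
                          family_size_probs = c("1" = 0.25, "2" = 0.13,
                                                "3" = 0.47, "4" = 0.10,
                                                "5" = 0.05),
                          allele_frequencies = default_allele_frequencies(),
                          cnv_events = default_cnv_events(),
                          lof_events = default_lof_events(),
                          medication_model = default_medication_model(),
                          fraction_with_medication_data = 0.359,
                          seed = 1L) {
  stopifnot(n_families >= 1, abs(sum(family_size_probs) - 1) < 1e-9,
            fraction_with_medication_data >= 0,
            fraction_with_medication_data <= 1)
  for (g in names(allele_frequencies)) {
    f <- allele_frequencies[[g]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("allele frequencies for ", g, " must be non-negative and sum to 1",
           call. = FALSE)
  }
  stopifnot(all(cnv_events$carrier_frequency >= 0),
            all(cnv_events$carrier_frequency <= 1),
            all(lof_events$carrier_frequency >= 0),
            all(lof_events$carrier_frequency <= 1))
  structure(list(n_families = n_families,
                 family_size_probs = family_size_probs,
                 allele_frequencies = allele_frequencies,
                 cnv_events = cnv_events, lof_events = lof_events,
                 medication_model = medication_model,
                 fraction_with_medication_data = fraction_with_medication_data,
                 seed = as.integer(seed)),
            class = "pgx_cohort_config")
}

draw_allele <- function(freqs) {
  sample(names(freqs), 1L, prob = freqs)
}

#' Generate a synthetic pedigree cohort with ground truth
#'
#' Families consist of an index patient and, depending on family size, a
#' mother, a father, and siblings. Founders draw star alleles independently
#' from the configured frequencies; offspring inherit one allele per
#' available parent (missing parents are replaced by population draws).
#' G6PD is X-linked: males carry a single maternal allele. CNV and
#' loss-of-function events are assigned to random carriers at the
#' configured per-individual carrier frequencies, and medications are
#' sampled for the medicated subcohort. Everything is reproducible under
#' the configured seed.
#'
#' @param config a `pgx_cohort_config`.
#' @return list of tibbles: `individuals` (pedigree + sex + medication
#'   availability), `diplotypes` (true per-gene allele pairs), `cnvs`,
#'   `lofs`, `medications`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pgx_cohort_config"))
  set.seed(config$seed)
  freqs <- config$allele_frequencies
  genes <- names(freqs)
  x_genes <- pgx_genes()$gene[pgx_genes()$x_linked]

  inds <- list()
  dips <- list()

  sizes <- as.integer(names(config$family_size_probs))
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%04d", f)
    k <- sample(sizes, 1L, prob = config$family_size_probs)
    has_father <- k >= 3
    has_mother <- k >= 2
    n_sibs <- max(0L, k - 3L)

    mk_id <- function(tag) paste0(fam, "_", tag)
    member <- function(id, role, sex, father, mother)
      tibble::tibble(individual_id = id, family_id = fam, role = role,
                     sex = sex, father_id = father, mother_id = mother)

    father_id <- if (has_father) mk_id("FA") else NA_character_
    mother_id <- if (has_mother) mk_id("MO") else NA_character_

    fam_members <- list()
    if (has_father)
      fam_members$fa <- member(father_id, "relative", "M", NA, NA)
    if (has_mother)
      fam_members$mo <- member(mother_id, "relative", "F", NA, NA)
    fam_members$idx <- member(mk_id("P1"), "index",
                              sample(c("M", "F"), 1L), father_id, mother_id)
    if (n_sibs > 0) for (s in seq_len(n_sibs))
      fam_members[[paste0("s", s)]] <- member(mk_id(sprintf("S%d", s)),
                                              "relative",
                                              sample(c("M", "F"), 1L),
                                              father_id, mother_id)
    fam_tbl <- dplyr::bind_rows(fam_members)
    inds[[f]] <- fam_tbl

    # founders first, then offspring inherit
    geno <- list()  # geno[[id]][[gene]] = character vector of alleles
    for (i in seq_len(nrow(fam_tbl))) {
      m <- fam_tbl[i, ]
      id <- m$individual_id
      geno[[id]] <- list()
      founder <- is.na(m$father_id) && is.na(m$mother_id)
      for (g in genes) {
        xl <- g %in% x_genes
        n_copies <- if (xl && m$sex == "M") 1L else 2L
        if (founder) {
          al <- replicate(n_copies, draw_allele(freqs[[g]]))
        } else {
          if (xl) {
            mat <- if (!is.na(m$mother_id))
              sample(geno[[m$mother_id]][[g]], 1L)
            else draw_allele(freqs[[g]])
            if (m$sex == "M") al <- mat
            else {
              pat <- if (!is.na(m$father_id)) geno[[m$father_id]][[g]][1]
                     else draw_allele(freqs[[g]])
              al <- c(mat, pat)
            }
          } else {
            mat <- if (!is.na(m$mother_id))
              sample(geno[[m$mother_id]][[g]], 1L)
            else draw_allele(freqs[[g]])
            pat <- if (!is.na(m$father_id))
              sample(geno[[m$father_id]][[g]], 1L)
            else draw_allele(freqs[[g]])
            al <- c(mat, pat)
          }
        }
        geno[[id]][[g]] <- al
      }
    }
    dips[[f]] <- dplyr::bind_rows(lapply(names(geno), function(id) {
      dplyr::bind_rows(lapply(genes, function(g) {
        al <- geno[[id]][[g]]
        tibble::tibble(individual_id = id, gene = g,
                       allele_1 = al[1],
                       allele_2 = if (length(al) > 1) al[2] else NA_character_)
      }))
    }))
  }

  individuals <- dplyr::bind_rows(inds)
  diplotypes <- dplyr::bind_rows(dips)
  n <- nrow(individuals)

  # structural / rare events on random carriers
  cnvs <- list()
  ev <- config$cnv_events
  for (i in seq_len(nrow(ev))) {
    carrier <- individuals$individual_id[stats::runif(n) < ev$carrier_frequency[i]]
    if (length(carrier))
      cnvs[[length(cnvs) + 1]] <- tibble::tibble(
        individual_id = carrier, gene = ev$gene[i], kind = ev$kind[i],
        exon_start = ev$exon_start[i], exon_end = ev$exon_end[i],
        split_read_support = TRUE,
        copy_state = if (ev$kind[i] == "deletion") 1L else 3L)
  }
  cnvs <- if (length(cnvs)) dplyr::bind_rows(cnvs) else
    tibble::tibble(individual_id = character(0), gene = character(0),
                   kind = character(0), exon_start = integer(0),
                   exon_end = integer(0), split_read_support = logical(0),
                   copy_state = integer(0))

  lofs <- list()
  lv <- config$lof_events
  for (i in seq_len(nrow(lv))) {
    v <- lof_variant(lv$gene[i], lv$lof_type[i], near_cds = lv$lof_cds[i])
    carrier <- individuals$individual_id[stats::runif(n) < lv$carrier_frequency[i]]
    if (length(carrier))
      lofs[[length(lofs) + 1]] <- tibble::tibble(
        individual_id = carrier, gene = lv$gene[i], chrom = v$chrom,
        pos = v$pos, ref = v$ref, alt = v$alt, dosage = 1L,
        population_af = v$population_af)
  }
  lofs <- if (length(lofs)) dplyr::bind_rows(lofs) else
    tibble::tibble(individual_id = character(0), gene = character(0),
                   chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), dosage = integer(0),
                   population_af = numeric(0))

  # medications
  medicated <- stats::runif(n) < config$fraction_with_medication_data
  individuals$has_medication_data <- medicated
  mm <- config$medication_model
  meds <- list()
  for (i in which(medicated)) {
    id <- individuals$individual_id[i]
    take <- names(mm$drug_probs)[stats::runif(length(mm$drug_probs)) <
                                   mm$drug_probs]
    n_other <- stats::rpois(1, mm$mean_nonguideline)
    if (n_other > 0)
      take <- c(take, sprintf("studydrug%02d", sample.int(50, n_other)))
    if (length(take))
      meds[[length(meds) + 1]] <- tibble::tibble(
        individual_id = id, drug = unique(take), source = "prior_report")
  }
  medications <- if (length(meds)) dplyr::bind_rows(meds) else
    tibble::tibble(individual_id = character(0), drug = character(0),
                   source = character(0))

  list(individuals = individuals, diplotypes = diplotypes, cnvs = cnvs,
       lofs = lofs, medications = medications)
}

#' Emit a synthetic cohort as standard input files
#'
#' Writes a multi-sample VCF (defining variants of every carried star
#' allele plus injected loss-of-function variants, with AF annotations), a
#' BED-like CNV segment table, a medications CSV, and a PED pedigree file.
#' All files round-trip through the pipeline readers.
#'
#' @param truth cohort from [generate_cohort()].
#' @param defs allele definitions.
#' @param dir output directory (created if needed).
#' @param config the generating config (for AF annotations of defining
#'   variants).
#' @return named list of file paths (vcf, cnv, medications, ped).
#' @export
emit_files <- function(truth, defs, dir,
                       config = cohort_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inds <- truth$individuals
  samples <- inds$individual_id

  # variant rows: all defining variants of defined alleles, plus LoFs
  dv <- defs$variants
  dv <- dv[order(dv$chrom, dv$pos, dv$alt), ]
  dv_key <- paste(dv$chrom, dv$pos, dv$ref, dv$alt)
  keep <- !duplicated(dv_key)
  sites <- tibble::tibble(chrom = dv$chrom[keep], pos = dv$pos[keep],
                          ref = dv$ref[keep], alt = dv$alt[keep])
  sites$af <- vapply(seq_len(nrow(sites)), function(i) {
    g <- sites$chrom[i]
    als <- unique(dv$allele[dv$chrom == sites$chrom[i] &
                            dv$pos == sites$pos[i] &
                            dv$alt == sites$alt[i]])
    f <- config$allele_frequencies[[g]]
    if (is.null(f)) return(NA_real_)
    sum(f[names(f) %in% als])
  }, numeric(1))

  lof_sites <- unique(truth$lofs[, c("chrom", "pos", "ref", "alt",
                                     "population_af")])
  if (nrow(lof_sites)) {
    names(lof_sites)[5] <- "af"
    sites <- dplyr::bind_rows(sites, lof_sites)
  }
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), ]

  # genotype matrix
  xg <- pgx_genes()$gene[pgx_genes()$x_linked]
  site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  gt <- matrix("0/0", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(NULL, samples))

  av <- defs$variants
  dip <- truth$diplotypes
  for (j in seq_along(samples)) {
    id <- samples[j]
    sex <- inds$sex[j]
    drows <- dip[dip$individual_id == id, ]
    dos <- integer(length(site_key))
    hemi <- logical(length(site_key))
    for (r in seq_len(nrow(drows))) {
      g <- drows$gene[r]
      for (a in c(drows$allele_1[r], drows$allele_2[r])) {
        if (is.na(a)) next
        va <- av[av$gene == g & av$allele == a, ]
        if (nrow(va) == 0) next
        idx <- match(paste(va$chrom, va$pos, va$ref, va$alt), site_key)
        dos[idx] <- dos[idx] + 1L
      }
      if (g %in% xg && sex == "M")
        hemi[sites$chrom == g] <- TRUE
    }
    lrows <- truth$lofs[truth$lofs$individual_id == id, ]
    if (nrow(lrows)) {
      idx <- match(paste(lrows$chrom, lrows$pos, lrows$ref, lrows$alt),
                   site_key)
      dos[idx] <- dos[idx] + lrows$dosage
    }
    gcol <- ifelse(hemi, as.character(pmin(dos, 1L)),
                   c("0/0", "0/1", "1/1")[pmin(dos, 2L) + 1L])
    gt[, j] <- gcol
  }

  meta <- c("##fileformat=VCFv4.2",
            "##source=starpgx_simulator",
            paste0("##contig=<ID=", unique(sites$chrom), ">"),
            "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- cbind(CHROM = sites$chrom, POS = as.character(sites$pos),
               ID = ".", REF = sites$ref, ALT = sites$alt, QUAL = ".",
               FILTER = "PASS",
               INFO = ifelse(is.na(sites$af), ".",
                             sprintf("AF=%g", sites$af)))
  gtm <- cbind(FORMAT = rep("GT", nrow(sites)), gt)
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gtm)
  vcf_path <- file.path(dir, "cohort.vcf.gz")
  vcfR::write.vcf(vcf, vcf_path)

  cnv_path <- file.path(dir, "cnvs.tsv")
  cn <- truth$cnvs
  if (nrow(cn) > 0) {
    model_starts <- vapply(cn$gene, function(g)
      gene_model(g)$exons$start[1], numeric(1))
    cnv_out <- data.frame(
      chrom = cn$gene,
      start = model_starts + (cn$exon_start - 1L) * 250L - 1L,
      end = model_starts + (cn$exon_end - 1L) * 250L + 150L,
      gene = cn$gene, kind = cn$kind, exon_start = cn$exon_start,
      exon_end = cn$exon_end, split_read_support = cn$split_read_support,
      copy_state = cn$copy_state, individual_id = cn$individual_id)
  } else {
    cnv_out <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), gene = character(0),
                          kind = character(0), exon_start = integer(0),
                          exon_end = integer(0),
                          split_read_support = logical(0),
                          copy_state = integer(0),
                          individual_id = character(0))
  }
  utils::write.table(cnv_out, cnv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  med_path <- file.path(dir, "medications.csv")
  utils::write.csv(truth$medications, med_path, row.names = FALSE)

  ped_path <- file.path(dir, "pedigree.ped")
  ped <- data.frame(
    family_id = inds$family_id, individual_id = inds$individual_id,
    father_id = ifelse(is.na(inds$father_id), "0", inds$father_id),
    mother_id = ifelse(is.na(inds$mother_id), "0", inds$mother_id),
    sex = ifelse(inds$sex == "M", 1L, 2L), phenotype = 0L)
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  list(vcf = vcf_path, cnv = cnv_path, medications = med_path, ped = ped_path)
}

#' Simulate and emit a cohort in one step
#'
#' @param config a `pgx_cohort_config`.
#' @param dir output directory.
#' @param defs allele definitions.
#' @return list with `truth` and `files`.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = tempfile("cohort"),
                            defs = load_allele_definitions()) {
  truth <- generate_cohort(config)
  files <- emit_files(truth, defs, dir, config)
  list(truth = truth, files = files)
}
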