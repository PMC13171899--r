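#' Read medication records
#'
#' CSV with columns `individual_id`, `drug`, `source` (one of
#' `prior_report`, `ongoing`, `recommended`). An individual is considered
#' exposed to a drug if it appears at least once under any source, so
#' records are deduplicated per (individual, canonical drug) before
#' gene-drug pairs are built; `source` is retained for provenance only.
#'
#' @param path CSV path.
#' @return tibble of medication records.
#' @export
read_medications <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "drug") %in% names(d)))
  if (!"source" %in% names(d)) d$source <- NA_character_
  tibble::as_tibble(d[, c("individual_id", "drug", "source")])
}

#' Build gene-drug pairs
#'
#' Joins each individual's deduplicated drug exposures with their phenotype
#' call at every gene implicated for that drug in the guideline table. One
#' drug yields one pair per implicated gene; drugs without guideline
#' coverage yield none and are reported in the `uncovered_drugs` attribute.
#' Individuals lacking a phenotype call for an implicated gene have that
#' pair skipped (reported in the `skipped` attribute).
#'
#' @param meds medication tibble (individual_id, drug, optional source).
#' @param phenotypes tibble with one row per (individual_id, gene):
#'   columns individual_id, gene, guideline_label (the phenotype label used
#'   for guideline lookup) and optionally phenotype, activity_score.
#' @param guideline a `pgx_guideline`.
#' @return tibble of gene-drug pairs: individual_id, drug, gene, phenotype,
#'   recommendation, actionable; attributes `uncovered_drugs` and `skipped`.
#' @export
build_gdps <- function(meds, phenotypes, guideline) {
  meds$drug <- normalize_drug(meds$drug, guideline$synonyms)
  meds <- unique(meds[, c("individual_id", "drug")])
  e <- guideline$entries

  rows <- list()
  uncovered <- character(0)
  skipped <- list()
  for (i in seq_len(nrow(meds))) {
    ind <- meds$individual_id[i]
    drug <- meds$drug[i]
    genes <- unique(e$gene[e$drug == drug])
    if (length(genes) == 0) {
      uncovered <- c(uncovered, drug)
      next
    }
    for (g in genes) {
      ph <- phenotypes[phenotypes$individual_id == ind &
                       phenotypes$gene == g, ]
      if (nrow(ph) == 0) {
        skipped[[length(skipped) + 1]] <- data.frame(individual_id = ind,
                                                     drug = drug, gene = g)
        next
      }
      label <- ph$guideline_label[1]
      entry <- lookup_recommendation(guideline, drug, g, label)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual_id = ind, drug = drug, gene = g, phenotype = label,
        recommendation = entry$recommendation,
        actionable = entry$actionable)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(individual_id = character(0), drug = character(0),
                   gene = character(0), phenotype = character(0),
                   recommendation = character(0), actionable = logical(0))
  attr(out, "uncovered_drugs") <- sort(unique(uncovered))
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped)
                          else NULL
  out
}

#' Classify a gene-drug pair as actionable
#'
#' A pair is actionable when its recommendation is dosing, alternate drug,
#' their combination, or an "other" recommendation judged actionable in the
#' guideline table. Indeterminate phenotypes are never actionable.
#'
#' @param recommendation category string(s).
#' @param other_actionable logical for `other` entries.
#' @return logical vector.
#' @export
classify_actionable <- function(recommendation, other_actionable = NA) {
  entry_actionable(recommendation, other_actionable)
}

#' Reconstruct the per-gene/drug/phenotype actionability table
#'
#' Machine-readable roll-up of gene-drug pairs in the layout of a
#' guideline-actionability incidence table: per-cell counts with actionable
#' sub-counts, per-drug and per-gene roll-ups, and grand totals.
#'
#' @param gdps tibble from [build_gdps()].
#' @return list with `cells`, `by_drug`, `by_gene`, `total_gdps`,
#'   `total_actionable`.
#' @export
reconstruct_incidence_table <- function(gdps) {
  cells <- gdps %>%
    dplyr::count(.data$gene, .data$drug, .data$phenotype,
                 .data$recommendation, .data$actionable, name = "n") %>%
    dplyr::arrange(.data$gene, .data$drug, .data$phenotype)
  by_drug <- gdps %>%
    dplyr::group_by(.data$gene, .data$drug) %>%
    dplyr::summarise(n = dplyr::n(), n_actionable = sum(.data$actionable),
                     .groups = "drop")
  by_gene <- gdps %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(n = dplyr::n(), n_actionable = sum(.data$actionable),
                     .groups = "drop") %>%
    dplyr::mutate(pct_actionable = ifelse(.data$n > 0,
                                          100 * .data$n_actionable / .data$n,
                                          0))
  list(cells = cells, by_drug = by_drug, by_gene = by_gene,
       total_gdps = nrow(gdps), total_actionable = sum(gdps$actionable))
}

#' Carrier and allele frequency conventions
#'
#' Structural-variant and rare-variant frequencies are reported under two
#' conventions: carriers per individuals (`carrier_pct`, the convention the
#' source tables print under the label "AF") and variant alleles per total
#' autosomal alleles (`allele_pct`, carriers / 2N assuming heterozygous
#' carriers).
#'
#' @param events tibble with at least `n_carriers`; any identifying columns
#'   are carried through.
#' @param n_individuals cohort size N.
#' @return `events` with `n`, `carrier_pct`, `allele_pct` appended.
#' @export
event_frequencies <- function(events, n_individuals) {
  events$n <- n_individuals
  events$carrier_pct <- 100 * events$n_carriers / n_individuals
  events$allele_pct <- 100 * events$n_carriers / (2 * n_individuals)
  events
}

#' Summarize a cohort
#'
#' Deterministic cohort-level tallies: total and actionable gene-drug
#' pairs, per-gene and per-drug roll-ups, mean and SD of per-individual
#' pair counts (computed over individuals carrying at least one pair,
#' matching the "across N individuals" convention), and the fractions of
#' individuals with at least one actionable variant / actionable pair.
#'
#' @param gdps tibble from [build_gdps()].
#' @param phenotypes phenotype tibble with `actionable_variant` column
#'   (optional; needed for the actionable-variant fraction).
#' @param n_individuals total cohort size.
#' @param n_with_medication_data size of the medicated subcohort.
#' @param sd_type "sample" (n-1 denominator, default) or "population".
#' @return list of summary statistics.
#' @export
summarize_cohort <- function(gdps, phenotypes = NULL,
                             n_individuals = NA_integer_,
                             n_with_medication_data = NA_integer_,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  sd_fun <- function(x) {
    if (length(x) < 2) return(NA_real_)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  per_ind <- gdps %>%
    dplyr::count(.data$individual_id, name = "n_gdps")
  per_ind_act <- gdps[gdps$actionable, ] %>%
    dplyr::count(.data$individual_id, name = "n_actionable")

  t1 <- reconstruct_incidence_table(gdps)
  frac_act_variant <- NA_real_
  if (!is.null(phenotypes) && "actionable_variant" %in% names(phenotypes) &&
      !is.na(n_individuals)) {
    carriers <- phenotypes %>%
      dplyr::group_by(.data$individual_id) %>%
      dplyr::summarise(any = any(.data$actionable_variant), .groups = "drop")
    frac_act_variant <- sum(carriers$any) / n_individuals
  }

  list(
    n_individuals = n_individuals,
    n_with_medication_data = n_with_medication_data,
    gdp_count = t1$total_gdps,
    actionable_gdp_count = t1$total_actionable,
    by_gene = t1$by_gene,
    by_drug = t1$by_drug,
    n_individuals_with_gdp = nrow(per_ind),
    n_individuals_with_actionable_gdp = nrow(per_ind_act),
    mean_gdps_per_individual = if (nrow(per_ind)) mean(per_ind$n_gdps)
                               else 0,
    sd_gdps_per_individual = sd_fun(per_ind$n_gdps),
    mean_actionable_gdps_per_individual =
      if (nrow(per_ind_act)) mean(per_ind_act$n_actionable) else 0,
    sd_actionable_gdps_per_individual = sd_fun(per_ind_act$n_actionable),
    fraction_with_actionable_gdp =
      if (!is.na(n_with_medication_data) && n_with_medication_data > 0)
        nrow(per_ind_act) / n_with_medication_data else NA_real_,
    fraction_with_actionable_variant = frac_act_variant
  )
}
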