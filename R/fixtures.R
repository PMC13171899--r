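# genomic position of a CDS coordinate in a toy gene model
genomic_from_cds <- function(model, cpos) {
  exon_i <- (cpos - 1L) %/% 150L + 1L
  model$exons$start[exon_i] + (cpos - 1L) %% 150L
}

#' Construct a loss-of-function variant in a toy gene model
#'
#' Builds a variant guaranteed to classify as HIGH impact under
#' [classify_consequence()]: a stop-gained substitution (TAC codon mutated
#' to TAA), a single-base deletion, or a single-base duplication, placed at
#' the codon nearest `near_cds`.
#'
#' @param gene gene symbol.
#' @param type one of "stop_gained", "frameshift_del", "frameshift_dup".
#' @param near_cds preferred CDS coordinate (defaults to mid-CDS).
#' @param population_af AF annotation to attach (default 0.001).
#' @return one-row variant tibble.
#' @export
lof_variant <- function(gene,
                        type = c("stop_gained", "frameshift_del",
                                 "frameshift_dup"),
                        near_cds = NULL, population_af = 0.001) {
  type <- match.arg(type)
  model <- gene_model(gene)
  len <- nchar(model$cds)
  if (is.null(near_cds)) near_cds <- len %/% 2L

  if (type == "stop_gained") {
    # TAC codons sit wherever the repeated block starts; mutate third base
    starts <- seq(4L, len - 2L, by = 3L)
    codons <- substring(model$cds, starts, starts + 2L)
    tac <- starts[codons == "TAC"]
    cpos <- tac[which.min(abs(tac - near_cds))] + 2L  # the C of TAC
    pos <- genomic_from_cds(model, cpos)
    return(variant_records(gene, pos, "C", "A", 1L, population_af))
  }
  cpos <- min(max(near_cds, 2L), len - 1L)
  pos <- genomic_from_cds(model, cpos)
  base <- substr(model$cds, cpos, cpos)
  if (type == "frameshift_del") {
    prev <- substr(model$cds, cpos - 1L, cpos - 1L)
    return(variant_records(gene, pos - 1L, paste0(prev, base), prev, 1L,
                           population_af))
  }
  variant_records(gene, pos, base, paste0(base, base), 1L, population_af)
}

#' Expand the bundled incidence-table counts into a fixture cohort
#'
#' The bundled `incidence_counts.tsv` records, for each (drug, gene,
#' phenotype), how many medicated individuals in the study cohort carried
#' that combination. This function expands it into explicit medication
#' records and phenotype calls (one pseudo-individual per counted unit) so
#' the gene-drug-pair machinery can reconstruct the table from first
#' principles.
#'
#' @param path counts TSV (drug, gene, phenotype, n).
#' @return list with `meds` and `phenotypes` tibbles and `counts` as read.
#' @export
incidence_cohort <- function(path = pgx_fixture("incidence_counts.tsv")) {
  counts <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  meds <- list()
  phen <- list()
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    for (j in seq_len(r$n)) {
      k <- k + 1L
      id <- sprintf("T1_%04d", k)
      meds[[k]] <- tibble::tibble(individual_id = id, drug = r$drug,
                                  source = "prior_report")
      score <- NA_real_
      ph <- r$phenotype
      if (r$gene == "CYP2C9" && grepl("^IM", ph))
        score <- if (grepl("1.5", ph, fixed = TRUE)) 1.5 else 1.0
      phen[[k]] <- tibble::tibble(
        individual_id = id, gene = r$gene,
        phenotype = if (r$gene == "CYP2C9" && grepl("^IM", ph)) "IM" else ph,
        activity_score = score, guideline_label = ph)
    }
  }
  list(meds = dplyr::bind_rows(meds), phenotypes = dplyr::bind_rows(phen),
       counts = tibble::as_tibble(counts))
}

#' The in-study CNV and rare-variant carriers
#'
#' Deterministic fixture of the 29 overlay cases interpreted in the study:
#' 12 deletion carriers (7 CYP2C19 exon 1-5, 3 COMT whole-gene, 2 CYP3A5
#' exons 5-7), 5 whole-gene amplification carriers (3 COMT, 1 CYP2B6 on
#' *1/*6, 1 CYP2C9 on *1/*1) and 12 rare high-impact variant carriers
#' (8 CYP3A5 frameshifts on *3/*3, 2 CYP3A5 stop-gained — one on *1/*3, one
#' with unstated prior — 1 CYP2C19 stop-gained on *1/*17, 1 SLCO1B1
#' frameshift with an ambiguous prior call).
#'
#' @return tibble with one row per carrier: case_id, gene, kind, prior
#'   alleles, CNV geometry or LoF variant type, ambiguity flags.
#' @export
overlay_case_fixture <- function() {
  del <- function(id, gene, a1, a2, es, ee, ambiguous = FALSE)
    tibble::tibble(case_id = id, gene = gene, kind = "deletion",
                   allele_1 = a1, allele_2 = a2, exon_start = es,
                   exon_end = ee, lof_type = NA_character_,
                   lof_cds = NA_integer_, ambiguous = ambiguous,
                   prior_known = TRUE)
  dup <- function(id, gene, a1, a2, ee)
    tibble::tibble(case_id = id, gene = gene, kind = "duplication",
                   allele_1 = a1, allele_2 = a2, exon_start = 1L,
                   exon_end = ee, lof_type = NA_character_,
                   lof_cds = NA_integer_, ambiguous = FALSE,
                   prior_known = TRUE)
  lof <- function(id, gene, a1, a2, type, cds, ambiguous = FALSE,
                  prior_known = TRUE)
    tibble::tibble(case_id = id, gene = gene, kind = "lof",
                   allele_1 = a1, allele_2 = a2, exon_start = NA_integer_,
                   exon_end = NA_integer_, lof_type = type,
                   lof_cds = as.integer(cds), ambiguous = ambiguous,
                   prior_known = prior_known)
  dplyr::bind_rows(
    del("del01", "CYP2C19", "*17", "*17", 1L, 5L),
    del("del02", "CYP2C19", "*17", "*17", 1L, 5L),
    del("del03", "CYP2C19", "*1", "*1", 1L, 5L),
    del("del04", "CYP2C19", "*1", "*1", 1L, 5L),
    del("del05", "CYP2C19", "*1", "*1", 1L, 5L),
    del("del06", "CYP2C19", "*1", "*1", 1L, 5L),
    del("del07", "CYP2C19", "*2B", "*2B", 1L, 5L),
    del("del08", "COMT", "Val", "Val", 1L, 6L),
    del("del09", "COMT", "Val", "Met", 1L, 6L),
    del("del10", "COMT", "Val", "Met", 1L, 6L),
    del("del11", "CYP3A5", "*3", "*3", 5L, 7L),
    del("del12", "CYP3A5", "*3", "*3", 5L, 7L),
    dup("amp01", "COMT", "Met", "Val", 6L),
    dup("amp02", "COMT", "Met", "Val", 6L),
    dup("amp03", "COMT", "Met", "Met", 6L),
    dup("amp04", "CYP2B6", "*1", "*6", 9L),
    dup("amp05", "CYP2C9", "*1", "*1", 9L),
    lof("rare01", "CYP3A5", "*3", "*3", "frameshift_dup", 247L),
    lof("rare02", "CYP3A5", "*3", "*3", "frameshift_dup", 247L),
    lof("rare03", "CYP3A5", "*3", "*3", "frameshift_del", 1372L),
    lof("rare04", "CYP3A5", "*3", "*3", "frameshift_del", 1372L),
    lof("rare05", "CYP3A5", "*3", "*3", "frameshift_del", 1372L),
    lof("rare06", "CYP3A5", "*3", "*3", "frameshift_del", 1372L),
    lof("rare07", "CYP3A5", "*3", "*3", "frameshift_del", 1372L),
    lof("rare08", "CYP3A5", "*3", "*3", "frameshift_del", 1372L),
    lof("rare09", "CYP3A5", "*1", "*3", "stop_gained", 746L),
    lof("rare10", "CYP3A5", NA, NA, "stop_gained", 746L,
        prior_known = FALSE),
    lof("rare11", "CYP2C19", "*1", "*17", "stop_gained", 463L),
    lof("rare12", "SLCO1B1", "*1", "*1", "frameshift_del", 1925L,
        ambiguous = TRUE)
  )
}

make_prior <- function(case, defs) {
  if (!case$prior_known) return(list(diplotype = NULL, phenotype = NULL))
  dip <- structure(list(
    gene = case$gene, allele_1 = case$allele_1, allele_2 = case$allele_2,
    hemizygous = FALSE, unexplained = FALSE,
    ambiguous_alternatives = if (case$ambiguous) list(c("?", "?"))
                             else list()),
    class = "pgx_diplotype")
  list(diplotype = dip, phenotype = assign_phenotype(dip, defs))
}

#' Replay the in-study overlay cases
#'
#' Runs every carrier of [overlay_case_fixture()] through the CNV filter and
#' the deletion / duplication / loss-of-function overlays.
#'
#' @param defs allele definitions.
#' @param guideline guideline table.
#' @return tibble: one overlay result row per case (case_id prepended).
#' @export
replay_overlay_cases <- function(defs = load_allele_definitions(),
                               guideline = load_guideline_table()) {
  cases <- overlay_case_fixture()
  out <- list()
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    prior <- make_prior(case, defs)
    if (case$kind %in% c("deletion", "duplication")) {
      cnv <- cnv_calls(case$gene, case$kind, case$exon_start, case$exon_end,
                       split_read_support = TRUE)
      cnv <- filter_cnv_calls(cnv)
      stopifnot(nrow(cnv) == 1)
      res <- if (case$kind == "deletion")
        apply_deletion_overlay(prior, cnv, defs, guideline)
      else apply_duplication_overlay(prior, cnv, defs, guideline)
    } else {
      v <- lof_variant(case$gene, case$lof_type, near_cds = case$lof_cds)
      rare <- filter_rare_high_impact(v, defs)
      stopifnot(nrow(rare) == 1)
      res <- apply_lof_overlay(prior, rare[1, ], defs, guideline)
    }
    res$case_id <- case$case_id
    out[[i]] <- res
  }
  dplyr::bind_rows(out)[, c("case_id", "gene", "kind", "prior", "candidates",
                            "n_candidates", "phenotype_modified",
                            "change_class")]
}

#' Summary counts over the replayed overlay cases
#'
#' @param results tibble from [replay_overlay_cases()].
#' @return named list: deletion recommendation changes, amplification
#'   phenotype modifications (and recommendation changes), definite and
#'   potential rare-variant changes.
#' @export
overlay_change_counts <- function(results = replay_overlay_cases()) {
  d <- results[results$kind == "deletion", ]
  a <- results[results$kind == "duplication", ]
  r <- results[results$kind == "lof", ]
  list(
    n_deletion_carriers = nrow(d),
    n_amplification_carriers = nrow(a),
    n_rare_variant_carriers = nrow(r),
    deletion_recommendation_changes =
      sum(d$change_class == "phenotype_and_recommendation"),
    amplification_phenotype_modifications = sum(a$phenotype_modified),
    amplification_recommendation_changes =
      sum(a$phenotype_modified &
            a$change_class %in% c("phenotype_and_recommendation", "potential")),
    rare_definite_changes =
      sum(r$change_class == "phenotype_and_recommendation"),
    rare_potential_changes = sum(r$change_class == "potential")
  )
}
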