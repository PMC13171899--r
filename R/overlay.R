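# -- toy transcript models -------------------------------------------------

# Standard genetic code, used only to distinguish stop-gained / missense /
# synonymous codon changes in the toy transcript models.
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Toy transcript model of a pharmacogene
#'
#' Each gene lives on its own synthetic contig (named after the gene) with
#' `n_exons` exons of 150 bp separated by 100 bp introns, the first exon
#' starting at position 1001, plus strand. The CDS is the exon
#' concatenation; its sequence is a deterministic repeat of a stop-free
#' codon block (ATG first, so every codon position is in a defined frame).
#' Real transcript models can be substituted by supplying the same structure.
#'
#' @param gene gene symbol.
#' @return list with `gene`, `contig`, `exons` (tibble exon/start/end) and
#'   `cds` (character scalar sequence).
#' @export
gene_model <- function(gene) {
  info <- gene_info(gene)
  n <- info$n_exons
  starts <- 1001L + (seq_len(n) - 1L) * 250L
  exons <- tibble::tibble(exon = seq_len(n), start = starts,
                          end = starts + 149L)
  len <- n * 150L
  block <- c("TAC", "GAC", "CTG", "AAA", "GGC", "TTC", "ATC", "GAA",
             "TGG", "CAG", "CCT", "GTA")
  codons <- c("ATG", rep(block, length.out = len / 3L - 1L))
  list(gene = gene, contig = gene, exons = exons,
       cds = paste(codons, collapse = ""))
}

# genomic position -> CDS coordinate (NA when intronic/intergenic)
cds_position <- function(model, pos) {
  e <- model$exons
  i <- which(pos >= e$start & pos <= e$end)
  if (length(i) == 0) return(NA_integer_)
  as.integer((i - 1L) * 150L + (pos - e$start[i]) + 1L)
}

#' Classify the predicted consequence of a variant
#'
#' A simplified consequence classifier over the toy transcript models:
#' frameshift (indel length not divisible by 3 inside the CDS), stop-gained,
#' start-lost, and splice-site (within 2 nt of an exon boundary, intronic
#' side) are HIGH impact; everything else (missense, synonymous, in-frame
#' indel, noncoding) is non-HIGH.
#'
#' @param variant one-row variant tibble (chrom, pos, ref, alt).
#' @param model gene model from [gene_model()]; defaults to the model of the
#'   gene whose contig matches `variant$chrom`.
#' @return tibble: impact ("HIGH"/"non-HIGH"), consequence, note.
#' @export
classify_consequence <- function(variant, model = NULL) {
  if (is.null(model)) {
    if (!variant$chrom %in% pgx_genes()$gene)
      return(tibble::tibble(impact = "non-HIGH", consequence = "noncoding",
                            note = "outside any gene model"))
    model <- gene_model(variant$chrom)
  }
  pos <- variant$pos
  ref <- variant$ref
  alt <- variant$alt
  e <- model$exons

  cpos <- cds_position(model, pos)
  if (is.na(cpos)) {
    near <- any((pos >= e$start - 2L & pos < e$start) |
                (pos > e$end & pos <= e$end + 2L))
    if (near)
      return(tibble::tibble(impact = "HIGH", consequence = "splice_site",
                            note = NA_character_))
    return(tibble::tibble(impact = "non-HIGH", consequence = "noncoding",
                          note = "outside exons"))
  }

  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L != 0L
    return(tibble::tibble(
      impact = if (shift) "HIGH" else "non-HIGH",
      consequence = if (shift) "frameshift" else "inframe_indel",
      note = NA_character_))
  }

  # SNV: rebuild the codon around the variant position
  codon_idx <- (cpos - 1L) %/% 3L
  off <- (cpos - 1L) %% 3L + 1L
  old_codon <- substr(model$cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  new_codon <- old_codon
  substr(new_codon, off, off) <- alt
  note <- if (substr(old_codon, off, off) != ref)
    "ref does not match model sequence" else NA_character_

  old_aa <- GENETIC_CODE_STD[[old_codon]]
  new_aa <- GENETIC_CODE_STD[[new_codon]]
  if (codon_idx == 0L && new_codon != "ATG")
    return(tibble::tibble(impact = "HIGH", consequence = "start_lost",
                          note = note))
  if (new_aa == "*" && old_aa != "*")
    return(tibble::tibble(impact = "HIGH", consequence = "stop_gained",
                          note = note))
  tibble::tibble(
    impact = "non-HIGH",
    consequence = if (old_aa == new_aa) "synonymous" else "missense",
    note = note)
}

# -- CNV handling ----------------------------------------------------------

#' Construct a table of CNV calls
#'
#' @param gene,kind,exon_start,exon_end,split_read_support,copy_state
#'   vectors of equal length; `kind` is "deletion" or "duplication".
#' @return tibble of CNV calls with derived `n_exons_affected` and
#'   `whole_gene`.
#' @export
cnv_calls <- function(gene, kind, exon_start, exon_end, split_read_support,
                      copy_state = ifelse(kind == "deletion", 1L, 3L)) {
  stopifnot(all(kind %in% c("deletion", "duplication")),
            all(exon_end >= exon_start), all(exon_start >= 1))
  total <- pgx_genes()$n_exons[match(gene, pgx_genes()$gene)]
  tibble::tibble(
    gene = gene, kind = kind,
    exon_start = as.integer(exon_start), exon_end = as.integer(exon_end),
    n_exons_affected = as.integer(exon_end - exon_start + 1L),
    whole_gene = exon_start == 1L & exon_end == total,
    split_read_support = as.logical(split_read_support),
    copy_state = as.integer(copy_state))
}

#' Read CNV calls from a BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open, informational), gene,
#' kind, exon_start, exon_end, split_read_support, copy_state, and
#' optionally individual_id.
#' @param path file path.
#' @export
read_cnv_calls <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  out <- cnv_calls(d$gene, d$kind, d$exon_start, d$exon_end,
                   d$split_read_support, d$copy_state)
  if ("individual_id" %in% names(d)) out$individual_id <- d$individual_id
  out
}

#' Filter CNV calls by size and split-read support
#'
#' Retains calls spanning strictly more than two exons (i.e. three or more)
#' AND carrying split-read support — the false-positive control applied
#' before any phenotype overlay.
#'
#' @param calls tibble from [cnv_calls()].
#' @return filtered tibble.
#' @export
filter_cnv_calls <- function(calls) {
  calls[calls$n_exons_affected >= 3L & calls$split_read_support, ,
        drop = FALSE]
}

# -- phenotype revision ----------------------------------------------------

# numeric function score of an allele: activity value when defined,
# otherwise a generic mapping of the function label
allele_score <- function(defs, gene, allele) {
  f <- allele_function(defs, gene, allele)
  if (!is.na(f$activity)) return(f$activity)
  c(no = 0, decreased = 0.5, normal = 1, increased = 1.5,
    indeterminate = NA_real_)[[f$fun]]
}

# phenotype of a pair given explicit function/activity descriptors;
# used by the deletion / loss-of-function overlays
phenotype_with_replacement <- function(defs, gene, kept_allele,
                                       bins = activity_bins()) {
  info <- gene_info(gene)
  fk <- allele_function(defs, gene, kept_allele)
  if (info$vocab == "activity") {
    score <- fk$activity + 0
    phen <- if (is.na(score)) "indeterminate" else bin_activity(gene, score, bins)
    return(list(phenotype = phen, activity_score = score))
  }
  if (info$vocab == "metabolizer")
    return(list(phenotype = pair_metabolizer(fk$fun, "no"),
                activity_score = NA_real_))
  if (info$vocab == "transporter")
    return(list(phenotype = pair_transporter(fk$fun, "no"),
                activity_score = NA_real_))
  if (info$vocab == "g6pd")
    return(list(phenotype = if (fk$fun %in% c("no", "decreased"))
      "deficient" else "variable", activity_score = NA_real_))
  list(phenotype = NA_character_, activity_score = NA_real_)
}

generic_rank_labels <- c("PM", "IM", "NM", "RM", "UM")

# three-copy scoring used by the duplication overlay; thresholds chosen so
# that two normal copies plus one map to RM and compensation of one
# decreased allele lands on NM (see methods vignette)
bin_three_copy <- function(total) {
  if (is.na(total)) return("indeterminate")
  if (total <= 0.5) "PM"
  else if (total <= 1.5) "IM"
  else if (total <= 2.25) "NM"
  else if (total <= 3.0) "RM"
  else "UM"
}

to_gene_scale <- function(gene, label) {
  info <- gene_info(gene)
  if (info$vocab == "transporter") {
    c(PM = "poor function", IM = "decreased function", NM = "normal function",
      RM = "increased function", UM = "increased function")[[label]]
  } else label
}

drugs_for_gene <- function(guideline, gene) {
  unique(guideline$entries$drug[guideline$entries$gene == gene])
}

# does the recommendation for any covered drug definitely differ between the
# prior label and the candidate label? Uncovered candidate labels (phenotypes
# no guideline row describes) never count as a definite change.
recommendation_changed <- function(guideline, gene, prior_label, cand_label,
                                   drugs = drugs_for_gene(guideline, gene)) {
  if (is.na(prior_label) || is.na(cand_label)) return(FALSE)
  for (d in drugs) {
    a <- lookup_recommendation(guideline, d, gene, prior_label, strict = FALSE)
    b <- lookup_recommendation(guideline, d, gene, cand_label, strict = FALSE)
    if (!is.null(a) && !is.null(b) &&
        a$recommendation != b$recommendation) return(TRUE)
  }
  FALSE
}

classify_change <- function(gene, prior_label, cand_labels, guideline,
                            ambiguous_prior = FALSE,
                            drugs = NULL) {
  info <- gene_info(gene)
  if (!info$guideline) {
    return(if (all(cand_labels == prior_label, na.rm = TRUE) &&
               !anyNA(cand_labels) && !is.na(prior_label)) "none"
           else "not_interpretable")
  }
  if (is.na(prior_label) || prior_label == "indeterminate")
    return("not_interpretable")
  if (is.null(drugs)) drugs <- drugs_for_gene(guideline, gene)
  cand_labels <- unique(unname(cand_labels))
  if (length(cand_labels) == 1 && identical(cand_labels, prior_label))
    return("none")
  changed <- vapply(cand_labels, function(cl)
    recommendation_changed(guideline, gene, prior_label, cl, drugs),
    logical(1))
  if (ambiguous_prior || length(cand_labels) > 1) {
    return(if (any(changed)) "potential" else "phenotype_only")
  }
  if (changed[1]) "phenotype_and_recommendation" else "phenotype_only"
}

overlay_result <- function(gene, kind, prior_label, candidates, change_class) {
  cand <- unique(unname(candidates))
  modified <- !anyNA(cand) && !is.na(prior_label) && length(cand) > 0 &&
    all(cand != prior_label)
  tibble::tibble(gene = gene, kind = kind, prior = prior_label,
                 candidates = paste(cand, collapse = "|"),
                 n_candidates = length(cand),
                 phenotype_modified = modified,
                 change_class = change_class)
}

#' Overlay a gene deletion on a called diplotype
#'
#' One allele of the prior diplotype is replaced by a no-function deletion
#' allele (whole-gene and function-abolishing partial deletions alike). A
#' homozygous prior yields a single deterministic candidate; a heterozygous
#' prior yields one candidate per choice of deleted allele — the deleted
#' allele's identity is never guessed. The change class compares guideline
#' recommendations between prior and candidates across all drugs covered for
#' the gene.
#'
#' @param prior list with `diplotype` (`pgx_diplotype`) and `phenotype`
#'   (row from [assign_phenotype()]); `diplotype` may carry
#'   `ambiguous_alternatives`.
#' @param cnv one-row CNV tibble (must have passed [filter_cnv_calls()]).
#' @param defs allele definitions; `guideline` guideline table.
#' @param guideline a `pgx_guideline`.
#' @return one-row overlay tibble: gene, kind, prior, candidates,
#'   n_candidates, change_class.
#' @export
apply_deletion_overlay <- function(prior, cnv, defs, guideline) {
  stopifnot(cnv$kind == "deletion")
  gene <- cnv$gene
  info <- gene_info(gene)
  if (!info$guideline || is.null(prior$diplotype))
    return(overlay_result(gene, "deletion", prior_label_of(prior),
                          NA_character_, "not_interpretable"))
  dip <- prior$diplotype
  prior_label <- prior$phenotype$guideline_label
  kept <- unique(c(dip$allele_2, dip$allele_1))  # delete the other one
  kept <- kept[!is.na(kept)]
  cands <- vapply(kept, function(k) {
    r <- phenotype_with_replacement(defs, gene, k)
    guideline_label(gene, r$phenotype, r$activity_score)
  }, character(1))
  cls <- classify_change(gene, prior_label, cands, guideline,
                         ambiguous_prior = length(dip$ambiguous_alternatives) > 0)
  overlay_result(gene, "deletion", prior_label, cands, cls)
}

prior_label_of <- function(prior) {
  if (!is.null(prior$phenotype)) prior$phenotype$guideline_label
  else NA_character_
}

#' Overlay a whole-gene duplication on a called diplotype
#'
#' Candidates are formed per choice of duplicated allele: the three-copy
#' function score (per-allele activity values, or a generic
#' no/decreased/normal/increased scale) is summed and binned, so an extra
#' normal-function copy pushes the phenotype one step toward increased
#' function while an extra copy of a decreased allele compensates toward
#' normal. Revised labels may fall outside the set of described two-copy
#' diplotypes (e.g. CYP2C9 rapid metabolizer), in which case no guideline
#' row covers them and the change cannot be a definite recommendation
#' change.
#'
#' @inheritParams apply_deletion_overlay
#' @export
apply_duplication_overlay <- function(prior, cnv, defs, guideline) {
  stopifnot(cnv$kind == "duplication")
  gene <- cnv$gene
  info <- gene_info(gene)
  if (!info$guideline || is.null(prior$diplotype) ||
      !info$vocab %in% c("metabolizer", "activity", "transporter"))
    return(overlay_result(gene, "duplication", prior_label_of(prior),
                          NA_character_, "not_interpretable"))
  dip <- prior$diplotype
  prior_label <- prior$phenotype$guideline_label
  pair <- c(dip$allele_1, dip$allele_2)
  pair <- pair[!is.na(pair)]
  base <- sum(vapply(pair, function(a) allele_score(defs, gene, a),
                     numeric(1)))
  cands <- vapply(unique(pair), function(d) {
    total <- base + allele_score(defs, gene, d)
    to_gene_scale(gene, bin_three_copy(total))
  }, character(1))
  cls <- classify_change(gene, prior_label, cands, guideline,
                         ambiguous_prior = length(dip$ambiguous_alternatives) > 0)
  overlay_result(gene, "duplication", prior_label, cands, cls)
}

#' Overlay a rare loss-of-function variant on a called diplotype
#'
#' The retained high-impact variant is assigned to each allele of the prior
#' diplotype in turn, converting that allele's function to no-function; the
#' candidate set and change classification follow the deletion overlay.
#'
#' @param prior as in [apply_deletion_overlay()]; a `NULL` diplotype (prior
#'   not determined) yields `not_interpretable`.
#' @param rare one-row tibble from [filter_rare_high_impact()].
#' @inheritParams apply_deletion_overlay
#' @export
apply_lof_overlay <- function(prior, rare, defs, guideline) {
  gene <- rare$gene
  info <- gene_info(gene)
  if (!info$guideline || is.null(prior$diplotype) ||
      is.null(prior$phenotype))
    return(overlay_result(gene, "lof", prior_label_of(prior),
                          NA_character_, "not_interpretable"))
  dip <- prior$diplotype
  prior_label <- prior$phenotype$guideline_label
  kept <- unique(c(dip$allele_2, dip$allele_1))
  kept <- kept[!is.na(kept)]
  cands <- vapply(kept, function(k) {
    r <- phenotype_with_replacement(defs, gene, k)
    guideline_label(gene, r$phenotype, r$activity_score)
  }, character(1))
  cls <- classify_change(gene, prior_label, cands, guideline,
                         ambiguous_prior = length(dip$ambiguous_alternatives) > 0)
  overlay_result(gene, "lof", prior_label, cands, cls)
}

#' Filter rare high-impact variants
#'
#' Retains variants that (1) classify as HIGH impact under
#' [classify_consequence()], (2) have a general-population allele frequency
#' below `af_threshold` (absent frequencies are treated as rare), and (3)
#' are not defining variants of any star allele — those are the remit of the
#' diplotype caller, not the rare-variant overlay.
#'
#' @param variants variant tibble (see [variant_records()]); `chrom` names
#'   the gene contig.
#' @param defs allele definitions.
#' @param af_threshold population-frequency cutoff (default 0.01).
#' @return tibble of retained calls with `gene`, `impact`, `consequence`
#'   columns appended.
#' @export
filter_rare_high_impact <- function(variants, defs, af_threshold = 0.01) {
  if (nrow(variants) == 0) {
    variants$gene <- character(0)
    variants$impact <- character(0)
    variants$consequence <- character(0)
    return(variants)
  }
  def_keys <- paste(defs$variants$chrom, defs$variants$pos,
                    defs$variants$ref, defs$variants$alt)
  keep <- logical(nrow(variants))
  impact <- consequence <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (paste(v$chrom, v$pos, v$ref, v$alt) %in% def_keys) next
    if (!is.na(v$population_af) && v$population_af >= af_threshold) next
    cc <- classify_consequence(v)
    impact[i] <- cc$impact
    consequence[i] <- cc$consequence
    keep[i] <- cc$impact == "HIGH"
  }
  out <- variants[keep, , drop = FALSE]
  out$gene <- out$chrom
  out$impact <- impact[keep]
  out$consequence <- consequence[keep]
  out
}
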