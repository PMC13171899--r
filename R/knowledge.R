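#' @importFrom dplyr %>%
NULL

recommendation_categories <- c("no_action", "dosing", "alternate_drug",
                               "dosing_alternate_drug", "other")

#' Load a star-allele definition table
#'
#' Reads a tab-separated allele definition file with columns
#' `gene, allele, chrom, pos, ref, alt, function, activity`. Each defining
#' variant occupies one row; the reference allele of a gene has a single row
#' with empty variant columns. Activity values are required only for
#' activity-score genes (CYP2D6, CYP2C9) and may be empty elsewhere.
#'
#' @param path path to the TSV file; defaults to the bundled knowledge base
#'   covering the twelve guideline genes plus COMT.
#' @return An object of class `pgx_allele_defs`: a list with an `alleles`
#'   tibble (one row per allele: gene, allele, fun, activity, n_defining) and
#'   a `variants` tibble (one row per defining variant).
#' @export
load_allele_definitions <- function(path = pgx_fixture("allele_definitions.tsv")) {
  if (!file.exists(path)) stop("allele definition file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  names(raw)[names(raw) == "function."] <- "fun"
  needed <- c("gene", "allele", "chrom", "pos", "ref", "alt", "fun", "activity")
  if (!all(needed %in% names(raw)))
    stop("allele definition file must have columns gene, allele, chrom, pos, ",
         "ref, alt, function, activity", call. = FALSE)
  raw$pos <- suppressWarnings(as.integer(raw$pos))
  raw$activity <- suppressWarnings(as.numeric(raw$activity))

  bad_fun <- setdiff(unique(raw$fun),
                     c("normal", "decreased", "no", "increased", "indeterminate"))
  if (length(bad_fun))
    stop("unknown function label(s): ", paste(bad_fun, collapse = ", "),
         call. = FALSE)

  is_var <- !is.na(raw$chrom) & !is.na(raw$pos)
  if (any(is_var & (is.na(raw$pos) | raw$pos < 1 | is.na(raw$ref) |
                    is.na(raw$alt) | raw$ref == raw$alt))) {
    i <- which(is_var & (raw$pos < 1 | is.na(raw$ref) | is.na(raw$alt) |
                         raw$ref == raw$alt))[1]
    stop(sprintf("malformed defining variant for %s %s (line %d)",
                 raw$gene[i], raw$allele[i], i + 1L), call. = FALSE)
  }

  alleles <- raw %>%
    dplyr::group_by(.data$gene, .data$allele) %>%
    dplyr::summarise(
      fun = dplyr::first(.data$fun),
      activity = dplyr::first(.data$activity),
      n_defining = sum(!is.na(.data$chrom)),
      .groups = "drop"
    )

  # one function/activity per allele
  chk <- raw %>%
    dplyr::group_by(.data$gene, .data$allele) %>%
    dplyr::summarise(nf = dplyr::n_distinct(.data$fun), .groups = "drop")
  if (any(chk$nf > 1)) {
    i <- which(chk$nf > 1)[1]
    stop(sprintf("allele %s %s has conflicting function labels",
                 chk$gene[i], chk$allele[i]), call. = FALSE)
  }

  variants <- raw[is_var, c("gene", "allele", "chrom", "pos", "ref", "alt")]
  variants <- tibble::as_tibble(variants)

  for (g in unique(alleles$gene)) {
    a <- alleles[alleles$gene == g, ]
    refs <- a$allele[a$n_defining == 0]
    if (length(refs) != 1)
      stop(sprintf("gene %s must have exactly one reference allele (found %d)",
                   g, length(refs)), call. = FALSE)
    v <- variants[variants$gene == g, ]
    keys <- vapply(split(v, v$allele), function(d)
      paste(sort(paste(d$chrom, d$pos, d$ref, d$alt)), collapse = ";"),
      character(1))
    if (anyDuplicated(keys)) {
      dup <- names(keys)[duplicated(keys)][1]
      stop(sprintf("gene %s: allele %s duplicates the defining variants of another allele",
                   g, dup), call. = FALSE)
    }
  }

  structure(list(alleles = alleles, variants = variants),
            class = "pgx_allele_defs")
}

#' @export
print.pgx_allele_defs <- function(x, ...) {
  cat(sprintf("<pgx_allele_defs> %d alleles across %d genes\n",
              nrow(x$alleles), length(unique(x$alleles$gene))))
  invisible(x)
}

#' Write a star-allele definition table
#'
#' Inverse of [load_allele_definitions()]; used for fixture generation and
#' round-trip validation.
#'
#' @param defs a `pgx_allele_defs` object.
#' @param path output path.
#' @export
write_allele_definitions <- function(defs, path) {
  rows <- list()
  for (i in seq_len(nrow(defs$alleles))) {
    a <- defs$alleles[i, ]
    v <- defs$variants[defs$variants$gene == a$gene &
                       defs$variants$allele == a$allele, ]
    if (nrow(v) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = a$gene, allele = a$allele, chrom = NA, pos = NA, ref = NA,
        alt = NA, `function` = a$fun, activity = a$activity,
        check.names = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        gene = a$gene, allele = a$allele, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt, `function` = a$fun, activity = a$activity,
        check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# alleles of one gene, reference allele first
gene_alleles <- function(defs, gene) {
  a <- defs$alleles[defs$alleles$gene == gene, ]
  if (nrow(a) == 0) stop("gene not in allele definitions: ", gene,
                         call. = FALSE)
  a[order(a$n_defining > 0, a$allele), ]
}

reference_allele <- function(defs, gene) {
  a <- gene_alleles(defs, gene)
  a$allele[a$n_defining == 0][1]
}

allele_function <- function(defs, gene, allele) {
  # sub-allele suffixes (e.g. *2B) normalize to the core allele for lookup
  a <- defs$alleles[defs$alleles$gene == gene, ]
  i <- match(allele, a$allele)
  if (is.na(i)) i <- match(core_allele(allele), a$allele)
  if (is.na(i)) stop(sprintf("allele %s not defined for %s", allele, gene),
                     call. = FALSE)
  list(fun = a$fun[i], activity = a$activity[i])
}

# *2B -> *2 ; non-star labels pass through
core_allele <- function(allele) {
  sub("^(\\*[0-9]+)[A-Za-z]+$", "\\1", allele)
}

#' Normalize a drug name
#'
#' Lowercases, trims, and resolves synonyms (paracetamol to acetaminophen,
#' citalopram/escitalopram to their shared guideline key, and common spelling
#' variants).
#'
#' @param drug character vector of drug names.
#' @param synonyms named character vector alias -> canonical; defaults to the
#'   bundled map.
#' @return canonical lowercase drug names.
#' @export
normalize_drug <- function(drug, synonyms = default_drug_synonyms()) {
  d <- tolower(trimws(drug))
  hit <- match(d, names(synonyms))
  d[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
  d
}

#' @rdname normalize_drug
#' @export
default_drug_synonyms <- function() {
  c(paracetamol = "acetaminophen",
    citalopram = "(es)citalopram",
    escitalopram = "(es)citalopram",
    "5-fluorouracil" = "fluorouracil",
    "(5-) fluorouracil" = "fluorouracil",
    allopurinole = "allopurinol",
    rosuvastation = "rosuvastatin")
}

#' Load a guideline recommendation table
#'
#' Reads the machine form of the drug/gene/phenotype recommendation table:
#' TSV columns `drug, gene, phenotype, recommendation, other_actionable`.
#' Recommendations are one of `no_action`, `dosing`, `alternate_drug`,
#' `dosing_alternate_drug`, `other`; an `other` entry is actionable only when
#' `other_actionable` is TRUE. Validation requires every (drug, gene) block
#' to cover the gene's full phenotype vocabulary.
#'
#' @param path TSV path; defaults to the bundled table.
#' @param synonyms drug synonym map.
#' @return A `pgx_guideline` object: list with `entries` tibble and
#'   `synonyms`.
#' @export
load_guideline_table <- function(path = pgx_fixture("guideline_table.tsv"),
                                 synonyms = default_drug_synonyms()) {
  if (!file.exists(path)) stop("guideline table not found: ", path,
                               call. = FALSE)
  e <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("drug", "gene", "phenotype", "recommendation", "other_actionable")
  if (!all(needed %in% names(e)))
    stop("guideline table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  e$drug <- normalize_drug(e$drug, synonyms)
  e$other_actionable <- as.logical(e$other_actionable)
  bad <- setdiff(unique(e$recommendation), recommendation_categories)
  if (length(bad))
    stop("unknown recommendation categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad_gene <- setdiff(unique(e$gene), pgx_genes()$gene)
  if (length(bad_gene))
    stop("unknown gene(s) in guideline table: ",
         paste(bad_gene, collapse = ", "), call. = FALSE)

  for (key in unique(paste(e$drug, e$gene, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    want <- guideline_phenotype_labels(parts[2])
    have <- e$phenotype[e$drug == parts[1] & e$gene == parts[2]]
    miss <- setdiff(want, have)
    if (length(miss))
      stop(sprintf("guideline table: %s/%s does not cover phenotype(s): %s",
                   parts[1], parts[2], paste(miss, collapse = ", ")),
           call. = FALSE)
    if (anyDuplicated(have))
      stop(sprintf("guideline table: duplicate phenotype rows for %s/%s",
                   parts[1], parts[2]), call. = FALSE)
  }
  e$actionable <- entry_actionable(e$recommendation, e$other_actionable)
  structure(list(entries = tibble::as_tibble(e), synonyms = synonyms),
            class = "pgx_guideline")
}

entry_actionable <- function(recommendation, other_actionable) {
  recommendation %in% c("dosing", "alternate_drug", "dosing_alternate_drug") |
    (recommendation == "other" & !is.na(other_actionable) & other_actionable)
}

#' @export
print.pgx_guideline <- function(x, ...) {
  cat(sprintf("<pgx_guideline> %d entries, %d drugs, %d genes\n",
              nrow(x$entries), length(unique(x$entries$drug)),
              length(unique(x$entries$gene))))
  invisible(x)
}

#' Look up the guideline recommendation for a drug/gene/phenotype
#'
#' Alias-resolved, case-insensitive. A drug or (drug, gene) combination
#' absent from the table returns `NULL` (an explicit "not covered" signal).
#' A covered drug queried with a phenotype label outside the gene's
#' vocabulary is an error in strict mode (it indicates a data bug, not a
#' non-covered drug); with `strict = FALSE` it returns `NULL`, which the
#' overlay engine uses for revised phenotypes that no guideline row
#' describes (e.g. CYP2C9 rapid metabolizer). `indeterminate` phenotypes
#' resolve to a synthesized `no_action` entry.
#'
#' @param guideline a `pgx_guideline` object.
#' @param drug drug name (any case, aliases allowed).
#' @param gene gene symbol.
#' @param phenotype phenotype label in the gene's guideline vocabulary.
#' @param strict error on unknown phenotype for a covered drug?
#' @return One-row tibble (drug, gene, phenotype, recommendation,
#'   other_actionable, actionable) or `NULL` when not covered.
#' @export
lookup_recommendation <- function(guideline, drug, gene, phenotype,
                                  strict = TRUE) {
  d <- normalize_drug(drug, guideline$synonyms)
  e <- guideline$entries
  block <- e[e$drug == d & e$gene == gene, ]
  if (nrow(block) == 0) return(NULL)
  if (identical(phenotype, "indeterminate")) {
    return(tibble::tibble(drug = d, gene = gene, phenotype = "indeterminate",
                          recommendation = "no_action",
                          other_actionable = NA, actionable = FALSE))
  }
  hit <- block[block$phenotype == phenotype, ]
  if (nrow(hit) == 0) {
    if (strict)
      stop(sprintf("phenotype '%s' not covered for %s/%s (data bug?)",
                   phenotype, d, gene), call. = FALSE)
    return(NULL)
  }
  hit
}

#' Path to a bundled knowledge-base fixture
#' @param file file name under the package's extdata directory.
#' @export
pgx_fixture <- function(file) {
  p <- system.file("extdata", file, package = "starpgx")
  if (p == "") stop("fixture not found: ", file, call. = FALSE)
  p
}
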