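#' Pharmacogene registry
#'
#' The pipeline interprets twelve genes with published CPIC/DPWG prescribing
#' guidelines plus COMT, which is carried through the structural-variant
#' overlay but has no guideline and therefore never yields an actionable call.
#'
#' Each gene is assigned a phenotype vocabulary:
#' \describe{
#'   \item{metabolizer}{UM/RM/NM/IM/PM (+ indeterminate), assigned from the
#'     function labels of the two alleles.}
#'   \item{activity}{metabolizer labels assigned by summing per-allele
#'     activity values and binning (CYP2D6, CYP2C9).}
#'   \item{transporter}{increased/normal/decreased/poor function (SLCO1B1).}
#'   \item{g6pd}{normal/variable/deficient with X-linked sex handling.}
#'   \item{single_variant}{wildtype / heterozygous / homozygous labels keyed
#'     to one tag variant (VKORC1 rs9923231, ABCG2 rs2231142).}
#'   \item{none}{no guideline vocabulary (COMT).}
#' }
#'
#' @return A tibble with one row per supported gene: `gene`, `vocab`,
#'   `x_linked`, `n_exons`, `guideline` (whether prescribing guidelines
#'   exist), and `tag_variant` (for single-variant genes).
#' @export
pgx_genes <- function() {
  tibble::tibble(
    gene = c("CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A5", "DPYD",
             "G6PD", "NUDT15", "TPMT", "SLCO1B1", "VKORC1", "ABCG2", "COMT"),
    vocab = c("metabolizer", "metabolizer", "activity", "activity",
              "metabolizer", "metabolizer", "g6pd", "metabolizer",
              "metabolizer", "transporter", "single_variant",
              "single_variant", "none"),
    x_linked = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE),
    n_exons = c(9L, 9L, 9L, 9L, 13L, 23L, 13L, 3L, 10L, 15L, 3L, 16L, 6L),
    guideline = c(rep(TRUE, 12), FALSE),
    tag_variant = c(rep(NA_character_, 10), "rs9923231", "rs2231142",
                    NA_character_)
  )
}

#' @rdname pgx_genes
#' @export
guideline_genes <- function() {
  g <- pgx_genes()
  g$gene[g$guideline]
}

gene_info <- function(gene) {
  g <- pgx_genes()
  i <- match(gene, g$gene)
  if (is.na(i)) stop("unknown gene: ", gene, call. = FALSE)
  g[i, ]
}

# Ordinal ranking of metabolizer labels, worst-to-best in terms of enzyme
# function; used by the overlay engine's monotonicity logic.
metabolizer_rank <- c(PM = 0, IM = 1, NM = 2, RM = 3, UM = 4)
transporter_rank <- c("poor function" = 0, "decreased function" = 1,
                      "normal function" = 2, "increased function" = 3)

#' Phenotype vocabulary of a gene
#'
#' @param gene gene symbol.
#' @return Character vector of valid phenotype labels (excluding
#'   "indeterminate", which every gene admits).
#' @export
phenotype_vocabulary <- function(gene) {
  info <- gene_info(gene)
  switch(info$vocab,
    # genes with no described increased-function allele span only NM/IM/PM
    metabolizer = if (gene %in% c("CYP3A5", "DPYD", "NUDT15", "TPMT"))
      c("NM", "IM", "PM") else c("UM", "RM", "NM", "IM", "PM"),
    activity = if (gene == "CYP2D6") c("UM", "NM", "IM", "PM")
               else c("NM", "IM", "PM"),
    transporter = names(transporter_rank),
    g6pd = c("normal", "variable", "deficient"),
    single_variant = c("wildtype",
                       paste(info$tag_variant, c("heterozygous", "homozygous"))),
    none = character(0)
  )
}

# Phenotype labels used as lookup keys in the guideline table. CYP2C9 splits
# IM by activity score because guidance differs between AS 1.5 and AS 1.0.
guideline_phenotype_labels <- function(gene) {
  if (gene == "CYP2C9") c("NM", "IM (AS 1.5)", "IM (AS 1)", "PM")
  else phenotype_vocabulary(gene)
}
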