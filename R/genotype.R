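#' Build a per-individual variant table
#'
#' Small-variant calls are carried as a tibble with one row per biallelic
#' record: `chrom`, `pos` (1-based), `ref`, `alt`, `dosage` (number of
#' alternate alleles: 0, 1 or 2; hemizygous calls use 1), and optional
#' `population_af` and `consequence` columns.
#'
#' @param chrom,pos,ref,alt,dosage vectors of equal length.
#' @param population_af optional general-population allele frequency.
#' @return tibble of variant records.
#' @export
variant_records <- function(chrom, pos, ref, alt, dosage,
                            population_af = NA_real_) {
  stopifnot(all(pos >= 1), all(ref != alt), all(dosage %in% 0:2))
  tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 dosage = as.integer(dosage),
                 population_af = as.numeric(population_af))
}

# deterministic ordering key for star alleles: reference first, then
# ascending star number, then other labels alphabetically
allele_sort_key <- function(allele, ref_allele) {
  num <- suppressWarnings(as.integer(sub("^\\*([0-9]+).*$", "\\1", allele)))
  ifelse(allele == ref_allele, "0|",
         ifelse(!is.na(num) & grepl("^\\*[0-9]", allele),
                sprintf("1|%08d|%s", num, allele),
                paste0("2|", allele)))
}

#' Call a star-allele diplotype from small-variant calls
#'
#' Scores every unordered pair of defined alleles of `gene` against the
#' observed alternate-allele dosages at the gene's defining positions. A pair
#' is feasible when it never predicts more alternate alleles than observed;
#' its score is the number of observed non-reference defining variants it
#' explains exactly. Among top-scoring feasible pairs, ties break toward the
#' pair with fewer non-reference alleles, then the lexicographically smallest
#' star numbers (the "default to *1" convention). If even the best pair
#' leaves an observed defining genotype unexplained, the call is flagged
#' `unexplained` and downstream phenotype assignment returns indeterminate.
#'
#' @param variants variant tibble (see [variant_records()]) restricted to one
#'   individual; records outside the gene's defining positions are ignored.
#' @param gene gene symbol.
#' @param defs allele definition table from [load_allele_definitions()].
#' @param hemizygous call a single allele (X-linked male)?
#' @return `pgx_diplotype` list: `gene`, `allele_1`, `allele_2` (NA when
#'   hemizygous), `hemizygous`, `unexplained`, `ambiguous_alternatives`
#'   (list of equally-scoring allele pairs, possibly empty).
#' @export
call_diplotype <- function(variants, gene, defs, hemizygous = FALSE) {
  av <- defs$variants[defs$variants$gene == gene, ]
  alleles <- gene_alleles(defs, gene)
  ref_allele <- reference_allele(defs, gene)

  vkey <- paste(av$chrom, av$pos, av$ref, av$alt)
  def_keys <- unique(vkey)

  obs <- integer(length(def_keys))
  names(obs) <- def_keys
  if (nrow(variants) > 0) {
    okey <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    dup <- okey[duplicated(okey)]
    if (length(dup)) {
      d <- variants$dosage[okey %in% dup]
      if (length(unique(d)) > 1)
        stop("conflicting genotypes at one position: ", dup[1], call. = FALSE)
    }
    hit <- match(okey, def_keys)
    for (i in which(!is.na(hit))) {
      dos <- variants$dosage[i]
      if (hemizygous) dos <- min(dos, 1L)
      obs[hit[i]] <- dos
    }
  }

  # per-allele indicator matrix over defining variant keys
  amat <- sapply(alleles$allele, function(a)
    as.integer(def_keys %in% vkey[av$allele == a]), simplify = FALSE)

  nonref_obs <- sum(obs > 0)

  if (hemizygous) {
    cand <- lapply(alleles$allele, function(a) list(a1 = a, a2 = NA_character_,
                                                    pred = amat[[a]]))
  } else {
    cand <- list()
    labs <- alleles$allele
    for (i in seq_along(labs)) for (j in i:length(labs)) {
      cand[[length(cand) + 1]] <- list(
        a1 = labs[i], a2 = labs[j],
        pred = if (length(def_keys)) amat[[labs[i]]] + amat[[labs[j]]]
               else integer(0))
    }
  }

  feasible <- vapply(cand, function(p) all(p$pred <= obs), logical(1))
  cand <- cand[feasible]
  score <- vapply(cand, function(p) sum(obs > 0 & p$pred == obs), integer(1))
  best <- max(score)
  top <- cand[score == best]

  rank_key <- vapply(top, function(p) {
    n_nonref <- sum(c(p$a1, p$a2) != ref_allele, na.rm = TRUE)
    paste(n_nonref,
          paste(sort(allele_sort_key(stats::na.omit(c(p$a1, p$a2)),
                                     ref_allele)), collapse = ","))
  }, character(1))
  ord <- order(rank_key)
  chosen <- top[[ord[1]]]
  alt_pairs <- lapply(top[ord[-1]], function(p)
    sort_pair(p$a1, p$a2, ref_allele))

  pair <- sort_pair(chosen$a1, chosen$a2, ref_allele)
  structure(list(gene = gene, allele_1 = pair[1],
                 allele_2 = if (hemizygous) NA_character_ else pair[2],
                 hemizygous = hemizygous,
                 unexplained = best < nonref_obs,
                 ambiguous_alternatives = alt_pairs),
            class = "pgx_diplotype")
}

sort_pair <- function(a1, a2, ref_allele) {
  if (is.na(a2)) return(c(a1, NA_character_))
  p <- c(a1, a2)
  p[order(allele_sort_key(p, ref_allele))]
}

#' @export
print.pgx_diplotype <- function(x, ...) {
  cat(sprintf("<pgx_diplotype> %s %s%s%s\n", x$gene, x$allele_1,
              if (is.na(x$allele_2)) " (hemizygous)"
              else paste0("/", x$allele_2),
              if (x$unexplained) " [unexplained variants]" else ""))
  invisible(x)
}

#' Default activity-score bins
#'
#' Per-gene bins mapping a diplotype activity-score sum to a metabolizer
#' label, CPIC-style. Each bin is `(lo, hi]`. The exact thresholds in force
#' at a given guideline version are an assumption documented in the methods
#' vignette; they are data, not code, and can be overridden.
#'
#' @return named list of data.frames with columns lo, hi, label.
#' @export
activity_bins <- function() {
  list(
    CYP2D6 = data.frame(lo = c(-1, 0, 1.2499, 2.25),
                        hi = c(0, 1.2499, 2.25, Inf),
                        label = c("PM", "IM", "NM", "UM")),
    CYP2C9 = data.frame(lo = c(-1, 0.5, 1.5),
                        hi = c(0.5, 1.5, Inf),
                        label = c("PM", "IM", "NM"))
  )
}

bin_activity <- function(gene, score, bins = activity_bins()) {
  b <- bins[[gene]]
  if (is.null(b)) stop("no activity bins for gene ", gene, call. = FALSE)
  i <- which(score > b$lo & score <= b$hi)[1]
  if (is.na(i)) "indeterminate" else b$label[i]
}

# generic function-pair -> metabolizer label
pair_metabolizer <- function(f1, f2) {
  fs <- sort(c(f1, f2))
  if (any(fs == "indeterminate")) return("indeterminate")
  low <- fs %in% c("no", "decreased")
  if (all(low)) return("PM")
  if (any(low)) return("IM")
  if (all(fs == "increased")) return("UM")
  if (any(fs == "increased")) return("RM")
  "NM"
}

pair_transporter <- function(f1, f2) {
  fs <- c(f1, f2)
  if (any(fs == "indeterminate")) return("indeterminate")
  low <- fs %in% c("no", "decreased")
  if (all(low)) return("poor function")
  if (any(low)) return("decreased function")
  if (all(fs == "increased")) return("increased function")
  if (any(fs == "increased")) return("increased function")
  "normal function"
}

#' Translate a diplotype into a phenotype call
#'
#' Function-pair genes map the two allele function labels through a fixed
#' lookup; activity-score genes (CYP2D6, CYP2C9) sum per-allele activity
#' values and bin them; SLCO1B1 uses the transporter vocabulary; G6PD
#' respects hemizygosity (deficient hemizygote/homozygote vs heterozygous
#' "variable"); VKORC1 and ABCG2 report tag-variant genotype labels. COMT
#' has no guideline vocabulary and returns an NA phenotype. An allele with
#' indeterminate function, or an unexplained diplotype, yields phenotype
#' "indeterminate" (never an error).
#'
#' @param diplotype a `pgx_diplotype`, or a list with fields gene, allele_1,
#'   allele_2, hemizygous.
#' @param defs allele definition table.
#' @param guideline optional guideline table; when supplied the
#'   `actionable_variant` flag is computed via [actionable_variant_flag()].
#' @param policy actionable-phenotype policy, see [actionable_variant_flag()].
#' @param bins activity-score bins, see [activity_bins()].
#' @return One-row tibble: gene, allele_1, allele_2, phenotype,
#'   activity_score, guideline_label, actionable_variant.
#' @export
assign_phenotype <- function(diplotype, defs, guideline = NULL,
                             policy = c("default", "include_normal"),
                             bins = activity_bins()) {
  policy <- match.arg(policy)
  gene <- diplotype$gene
  info <- gene_info(gene)
  hemi <- isTRUE(diplotype$hemizygous)
  a1 <- diplotype$allele_1
  a2 <- diplotype$allele_2
  unexplained <- isTRUE(diplotype$unexplained)

  f1 <- allele_function(defs, gene, a1)
  f2 <- if (hemi) NULL else allele_function(defs, gene, a2)

  score <- NA_real_
  if (unexplained) {
    phen <- "indeterminate"
  } else if (info$vocab == "activity") {
    score <- f1$activity + if (hemi) 0 else f2$activity
    phen <- if (is.na(score)) "indeterminate" else bin_activity(gene, score, bins)
  } else if (info$vocab == "metabolizer") {
    phen <- pair_metabolizer(f1$fun, if (hemi) f1$fun else f2$fun)
  } else if (info$vocab == "transporter") {
    phen <- pair_transporter(f1$fun, f2$fun)
  } else if (info$vocab == "g6pd") {
    def1 <- f1$fun %in% c("no", "decreased")
    if (hemi) {
      phen <- if (def1) "deficient" else "normal"
    } else {
      def2 <- f2$fun %in% c("no", "decreased")
      phen <- if (def1 && def2) "deficient"
              else if (def1 || def2) "variable" else "normal"
    }
  } else if (info$vocab == "single_variant") {
    tag <- info$tag_variant
    n_tag <- sum(c(a1, a2) == tag, na.rm = TRUE)
    phen <- if (n_tag == 0) "wildtype"
            else paste(tag, if (n_tag == 1) "heterozygous" else "homozygous")
  } else {
    phen <- NA_character_
  }

  glabel <- guideline_label(gene, phen, score)
  out <- tibble::tibble(
    gene = gene, allele_1 = a1, allele_2 = a2, phenotype = phen,
    activity_score = score, guideline_label = glabel,
    actionable_variant = FALSE)
  if (!is.null(guideline))
    out$actionable_variant <- actionable_variant_flag(out, guideline, policy)
  out
}

# phenotype label used as guideline lookup key; CYP2C9 IM keeps its
# activity-score split (guidance differs between AS 1.5 and AS 1.0)
guideline_label <- function(gene, phenotype, score = NA_real_) {
  if (is.na(phenotype)) return(NA_character_)
  if (gene == "CYP2C9" && phenotype == "IM") {
    if (!is.na(score) && score > 1.25) "IM (AS 1.5)" else "IM (AS 1)"
  } else phenotype
}

normalish_labels <- c("NM", "normal function", "normal", "wildtype")

#' Flag a phenotype as an actionable variant
#'
#' Default policy: a phenotype is an actionable variant when it is
#' non-normal, non-indeterminate, and at least one guideline entry for that
#' (gene, phenotype) recommends a therapy adjustment. The `include_normal`
#' policy also counts normal phenotypes with actionable entries (e.g.
#' pantoprazole recommends a dosing strategy even for CYP2C19 NM).
#'
#' @param phenotype_call one-row tibble from [assign_phenotype()].
#' @param guideline a `pgx_guideline`.
#' @param policy "default" or "include_normal".
#' @return logical.
#' @export
actionable_variant_flag <- function(phenotype_call, guideline,
                                    policy = c("default", "include_normal")) {
  policy <- match.arg(policy)
  gene <- phenotype_call$gene
  label <- phenotype_call$guideline_label
  if (is.na(label) || label == "indeterminate") return(FALSE)
  if (policy == "default" && label %in% normalish_labels) return(FALSE)
  e <- guideline$entries
  any(e$gene == gene & e$phenotype == label & e$actionable)
}
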