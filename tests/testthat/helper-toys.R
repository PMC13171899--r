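# Shared fixtures: bundled knowledge bases loaded once per test run
defs_kb <- load_allele_definitions()
guideline_kb <- load_guideline_table()

# Write a toy allele-definition TSV and return its path.
# `rows` is a data.frame with columns gene, allele, chrom, pos, ref, alt,
# fun, activity (variant columns NA for the reference allele).
toy_defs_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  names(rows)[names(rows) == "fun"] <- "function"
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

toy_row <- function(gene, allele, fun, pos = NA, ref = NA, alt = NA,
                    activity = NA) {
  data.frame(gene = gene, allele = allele,
             chrom = ifelse(is.na(pos), NA, gene), pos = pos, ref = ref,
             alt = alt, fun = fun, activity = activity,
             stringsAsFactors = FALSE)
}

# Random toy definition table on gene CYP2C19's contig for property tests:
# k alleles over a pool of at most 6 defining positions, distinct sets.
random_toy_defs <- function(n_alleles = sample(2:5, 1), n_pos = 6) {
  pool_pos <- 1001 + seq_len(n_pos) * 7
  repeat {
    rows <- list(toy_row("CYP2C19", "*1", "normal"))
    sets <- list()
    ok <- TRUE
    for (a in seq_len(n_alleles - 1)) {
      nm <- paste0("*", a + 1)
      idx <- sort(sample(n_pos, sample(1:3, 1)))
      key <- paste(idx, collapse = ",")
      if (key %in% unlist(sets)) { ok <- FALSE; break }
      sets[[a]] <- key
      fun <- sample(c("normal", "decreased", "no", "increased"), 1)
      for (i in idx)
        rows[[length(rows) + 1]] <- toy_row("CYP2C19", nm, fun,
                                            pos = pool_pos[i], ref = "A",
                                            alt = "T")
    }
    if (ok) break
  }
  list(defs = load_allele_definitions(toy_defs_file(dplyr::bind_rows(rows))),
       pool = data.frame(chrom = "CYP2C19", pos = pool_pos, ref = "A",
                         alt = "T"))
}

# Independent brute-force diplotype oracle: exhaustive nested-loop
# enumeration of allele pairs scored by the explanation criterion, ranked
# by (score desc, non-reference alleles asc, star numbers asc).
oracle_diplotype <- function(obs_dosage, defs, gene = "CYP2C19") {
  av <- defs$variants[defs$variants$gene == gene, ]
  alleles <- sort(unique(defs$alleles$allele[defs$alleles$gene == gene]))
  keys <- names(obs_dosage)
  member <- function(a) as.integer(keys %in%
                                     paste(av$chrom, av$pos, av$ref,
                                           av$alt)[av$allele == a])
  num <- function(x) as.integer(sub("\\*", "", x))
  cand <- list()
  for (a in alleles) for (b in alleles) {
    if (num(a) > num(b)) next
    pred <- member(a) + member(b)
    if (any(pred > obs_dosage)) next
    sc <- sum(obs_dosage > 0 & pred == obs_dosage)
    cand[[length(cand) + 1]] <- data.frame(
      a = a, b = b, score = sc, n_nonref = sum(c(a, b) != "*1"),
      k1 = min(num(a), num(b)), k2 = max(num(a), num(b)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$n_nonref, cand$k1, cand$k2), ]
  cand[1, ]
}

# variant tibble from a named dosage vector over a position pool
variants_from_dosage <- function(obs_dosage, pool) {
  keys <- paste(pool$chrom, pool$pos, pool$ref, pool$alt)
  d <- obs_dosage[keys]
  d[is.na(d)] <- 0L
  keep <- d > 0
  variant_records(pool$chrom[keep], pool$pos[keep], pool$ref[keep],
                  pool$alt[keep], d[keep])
}

# convenience: phenotype from explicit alleles
toy_phenotype <- function(gene, a1, a2, defs = defs_kb,
                          guideline = guideline_kb, ...) {
  dip <- structure(list(gene = gene, allele_1 = a1, allele_2 = a2,
                        hemizygous = is.na(a2), unexplained = FALSE,
                        ambiguous_alternatives = list()),
                   class = "pgx_diplotype")
  assign_phenotype(dip, defs, guideline = guideline, ...)
}

toy_prior <- function(gene, a1, a2, defs = defs_kb, ambiguous = FALSE) {
  dip <- structure(list(gene = gene, allele_1 = a1, allele_2 = a2,
                        hemizygous = FALSE, unexplained = FALSE,
                        ambiguous_alternatives = if (ambiguous)
                          list(c("?", "?")) else list()),
                   class = "pgx_diplotype")
  list(diplotype = dip, phenotype = assign_phenotype(dip, defs))
}
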