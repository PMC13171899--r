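test_that("CNV filter enforces size and split-read support jointly", {
  # enumerate the 2x2 of {2-exon, 3-exon} x {split support, none}
  calls <- cnv_calls(
    gene = rep("CYP2C19", 4), kind = rep("deletion", 4),
    exon_start = c(1, 1, 1, 1), exon_end = c(2, 3, 2, 3),
    split_read_support = c(TRUE, TRUE, FALSE, FALSE))
  kept <- filter_cnv_calls(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$exon_end, 3)
  expect_true(kept$split_read_support)

  # the in-study exon 1-5 deletion passes; a whole-gene call without
  # split reads does not
  expect_equal(nrow(filter_cnv_calls(
    cnv_calls("CYP2C19", "deletion", 1, 5, TRUE))), 1)
  expect_equal(nrow(filter_cnv_calls(
    cnv_calls("COMT", "deletion", 1, 6, FALSE))), 0)
})

test_that("consequence classifier separates HIGH from non-HIGH changes", {
  # single-base duplication in the CDS: frameshift
  fs <- lof_variant("CYP3A5", "frameshift_dup", near_cds = 247)
  expect_equal(classify_consequence(fs)$impact, "HIGH")
  expect_equal(classify_consequence(fs)$consequence, "frameshift")

  # G>T style stop gain
  sg <- lof_variant("CYP2C19", "stop_gained", near_cds = 463)
  expect_equal(classify_consequence(sg)$consequence, "stop_gained")

  # synonymous: CTG -> CTA at the third base of codon 4 (CDS pos 12)
  model <- gene_model("CYP2C19")
  expect_equal(substr(model$cds, 10, 12), "CTG")
  syn <- variant_records("CYP2C19", model$exons$start[1] + 11L, "G", "A", 1L)
  expect_equal(classify_consequence(syn)$consequence, "synonymous")
  expect_equal(classify_consequence(syn)$impact, "non-HIGH")

  # missense: TAC -> GAC at CDS pos 4
  mis <- variant_records("CYP2C19", model$exons$start[1] + 3L, "T", "G", 1L)
  expect_equal(classify_consequence(mis)$consequence, "missense")

  # splice site: 1 nt upstream of exon 2; deeper intron is noncoding
  spl <- variant_records("CYP2C19", model$exons$start[2] - 1L, "A", "G", 1L)
  expect_equal(classify_consequence(spl)$consequence, "splice_site")
  expect_equal(classify_consequence(spl)$impact, "HIGH")
  deep <- variant_records("CYP2C19", model$exons$start[2] - 50L, "A", "G", 1L)
  expect_equal(classify_consequence(deep)$impact, "non-HIGH")

  # in-frame 3 bp deletion is non-HIGH
  inframe <- variant_records("CYP2C19", model$exons$start[1] + 30L, "GACC",
                             "G", 1L)
  expect_equal(classify_consequence(inframe)$consequence, "inframe_indel")

  # start loss
  sl <- variant_records("CYP2C19", model$exons$start[1], "A", "C", 1L)
  expect_equal(classify_consequence(sl)$consequence, "start_lost")
})

test_that("rare-variant filter applies impact, frequency and star-exclusion", {
  sg <- lof_variant("CYP2C19", "stop_gained", near_cds = 463,
                    population_af = 0.001)
  expect_equal(nrow(filter_rare_high_impact(sg, defs_kb)), 1)

  common <- sg
  common$population_af <- 0.05
  expect_equal(nrow(filter_rare_high_impact(common, defs_kb)), 0)

  # absent AF treated as rare
  noaf <- sg
  noaf$population_af <- NA_real_
  expect_equal(nrow(filter_rare_high_impact(noaf, defs_kb)), 1)

  # a defining variant of a known star allele is excluded even at low AF
  v3 <- defs_kb$variants[defs_kb$variants$gene == "CYP3A5" &
                         defs_kb$variants$allele == "*3", ][1, ]
  def_var <- variant_records(v3$chrom, v3$pos, v3$ref, v3$alt, 1L, 0.001)
  expect_equal(nrow(filter_rare_high_impact(def_var, defs_kb)), 0)

  # a non-HIGH missense at low AF is excluded
  model <- gene_model("CYP2C19")
  mis <- variant_records("CYP2C19", model$exons$start[1] + 3L, "T", "G", 1L,
                         0.001)
  expect_equal(nrow(filter_rare_high_impact(mis, defs_kb)), 0)
})

del_ex15 <- filter_cnv_calls(cnv_calls("CYP2C19", "deletion", 1, 5, TRUE))

test_that("deletion overlay revises phenotypes and classifies the change", {
  # UM collapses to IM with a recommendation change
  res <- apply_deletion_overlay(toy_prior("CYP2C19", "*17", "*17"),
                                del_ex15, defs_kb, guideline_kb)
  expect_equal(res$candidates, "IM")
  expect_equal(res$n_candidates, 1)
  expect_equal(res$change_class, "phenotype_and_recommendation")

  # NM likewise
  res <- apply_deletion_overlay(toy_prior("CYP2C19", "*1", "*1"),
                                del_ex15, defs_kb, guideline_kb)
  expect_equal(res$candidates, "IM")
  expect_equal(res$change_class, "phenotype_and_recommendation")

  # PM stays PM: no change
  res <- apply_deletion_overlay(toy_prior("CYP2C19", "*2B", "*2B"),
                                del_ex15, defs_kb, guideline_kb)
  expect_equal(res$change_class, "none")

  # COMT has no guideline: not interpretable
  comt <- filter_cnv_calls(cnv_calls("COMT", "deletion", 1, 6, TRUE))
  res <- apply_deletion_overlay(toy_prior("COMT", "Val", "Val"),
                                comt, defs_kb, guideline_kb)
  expect_equal(res$change_class, "not_interpretable")
})

test_that("duplication overlay carries allele-choice ambiguity as candidates", {
  dup <- function(g, n) filter_cnv_calls(cnv_calls(g, "duplication", 1, n,
                                                   TRUE))
  # CYP2C9 *1/*1: deterministic RM candidate; RM has no guideline rows, so
  # the phenotype changes without a definite recommendation change
  res <- apply_duplication_overlay(toy_prior("CYP2C9", "*1", "*1"),
                                   dup("CYP2C9", 9), defs_kb, guideline_kb)
  expect_equal(res$candidates, "RM")
  expect_true(res$phenotype_modified)
  expect_equal(res$change_class, "phenotype_only")

  # CYP2B6 *1/*6: candidates depend on which allele is duplicated
  res <- apply_duplication_overlay(toy_prior("CYP2B6", "*1", "*6"),
                                   dup("CYP2B6", 9), defs_kb, guideline_kb)
  expect_setequal(strsplit(res$candidates, "|", fixed = TRUE)[[1]],
                  c("NM", "RM"))
  expect_true(res$phenotype_modified)
  expect_equal(res$change_class, "potential")

  res <- apply_duplication_overlay(toy_prior("COMT", "Met", "Met"),
                                   dup("COMT", 6), defs_kb, guideline_kb)
  expect_equal(res$change_class, "not_interpretable")
})

test_that("loss-of-function overlay assigns the variant to each allele in turn", {
  sg19 <- filter_rare_high_impact(
    lof_variant("CYP2C19", "stop_gained", near_cds = 463), defs_kb)
  res <- apply_lof_overlay(toy_prior("CYP2C19", "*1", "*17"), sg19[1, ],
                           defs_kb, guideline_kb)
  expect_equal(res$candidates, "IM")
  expect_equal(res$change_class, "phenotype_and_recommendation")

  fs35 <- filter_rare_high_impact(
    lof_variant("CYP3A5", "frameshift_del", near_cds = 1372), defs_kb)
  res <- apply_lof_overlay(toy_prior("CYP3A5", "*3", "*3"), fs35[1, ],
                           defs_kb, guideline_kb)
  expect_equal(res$change_class, "none")

  sg35 <- filter_rare_high_impact(
    lof_variant("CYP3A5", "stop_gained", near_cds = 746), defs_kb)
  res <- apply_lof_overlay(toy_prior("CYP3A5", "*1", "*3"), sg35[1, ],
                           defs_kb, guideline_kb)
  expect_setequal(strsplit(res$candidates, "|", fixed = TRUE)[[1]],
                  c("IM", "PM"))
  expect_equal(res$change_class, "potential")

  # unknown prior diplotype cannot be interpreted
  res <- apply_lof_overlay(list(diplotype = NULL, phenotype = NULL),
                           sg35[1, ], defs_kb, guideline_kb)
  expect_equal(res$change_class, "not_interpretable")

  # ambiguous prior caps the classification at potential
  fs_sl <- filter_rare_high_impact(
    lof_variant("SLCO1B1", "frameshift_del", near_cds = 1925), defs_kb)
  res <- apply_lof_overlay(toy_prior("SLCO1B1", "*1", "*1", ambiguous = TRUE),
                           fs_sl[1, ], defs_kb, guideline_kb)
  expect_equal(res$candidates, "decreased function")
  expect_equal(res$change_class, "potential")
})

test_that("overlay candidate counts and deletion monotonicity hold generally", {
  rank5 <- c(PM = 0, IM = 1, NM = 2, RM = 3, UM = 4, indeterminate = NA)
  alleles <- c("*1", "*2", "*3", "*17")
  for (a1 in alleles) for (a2 in alleles) {
    prior <- toy_prior("CYP2C19", a1, a2)
    res <- apply_deletion_overlay(prior, del_ex15, defs_kb, guideline_kb)
    if (a1 == a2) expect_equal(res$n_candidates, 1)
    expect_lte(res$n_candidates, 2)
    for (cand in strsplit(res$candidates, "|", fixed = TRUE)[[1]]) {
      expect_lte(rank5[[cand]], rank5[[prior$phenotype$phenotype]])
    }
  }
})

test_that("replaying the in-study carriers reproduces the reported change counts", {
  counts <- overlay_change_counts(replay_overlay_cases(defs_kb, guideline_kb))
  expect_equal(counts$n_deletion_carriers, 12)
  expect_equal(counts$n_amplification_carriers, 5)
  expect_equal(counts$n_rare_variant_carriers, 12)
  expect_equal(counts$deletion_recommendation_changes, 6)
  expect_equal(counts$amplification_phenotype_modifications, 2)
  expect_equal(counts$amplification_recommendation_changes, 1)
  expect_equal(counts$rare_definite_changes, 1)
  expect_equal(counts$rare_potential_changes, 2)
})
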