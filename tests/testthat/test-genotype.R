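empty_vars <- variant_records(character(0), integer(0), character(0),
                              character(0), integer(0))

test_that("reference and homozygous diplotypes are called from plain dosages", {
  dip <- call_diplotype(empty_vars, "CYP2C19", defs_kb)
  expect_equal(c(dip$allele_1, dip$allele_2), c("*1", "*1"))
  expect_false(dip$unexplained)

  # homozygous for the CYP3A5 *3 defining variant
  v3 <- defs_kb$variants[defs_kb$variants$gene == "CYP3A5" &
                         defs_kb$variants$allele == "*3", ]
  vars <- variant_records(v3$chrom, v3$pos, v3$ref, v3$alt, 2L)
  dip <- call_diplotype(vars, "CYP3A5", defs_kb)
  expect_equal(c(dip$allele_1, dip$allele_2), c("*3", "*3"))

  # compound heterozygote *2/*17
  v <- defs_kb$variants[defs_kb$variants$gene == "CYP2C19" &
                        defs_kb$variants$allele %in% c("*2", "*17"), ]
  vars <- variant_records(v$chrom, v$pos, v$ref, v$alt, 1L)
  dip <- call_diplotype(vars, "CYP2C19", defs_kb)
  expect_setequal(c(dip$allele_1, dip$allele_2), c("*2", "*17"))
})

test_that("conflicting genotypes at one position raise an input error", {
  v3 <- defs_kb$variants[defs_kb$variants$gene == "CYP3A5" &
                         defs_kb$variants$allele == "*3", ]
  vars <- dplyr::bind_rows(
    variant_records(v3$chrom, v3$pos, v3$ref, v3$alt, 1L),
    variant_records(v3$chrom, v3$pos, v3$ref, v3$alt, 2L))
  expect_error(call_diplotype(vars, "CYP3A5", defs_kb), "conflicting")
})

test_that("an observed genotype no allele pair explains flags the call", {
  # a defining-position variant pattern not matching any pair: *2 het plus
  # *3 hom cannot be explained by two alleles
  v <- defs_kb$variants[defs_kb$variants$gene == "CYP2C19", ]
  v2 <- v[v$allele == "*2", ]
  v3 <- v[v$allele == "*3", ]
  vars <- dplyr::bind_rows(
    variant_records(v2$chrom, v2$pos, v2$ref, v2$alt, 2L),
    variant_records(v3$chrom, v3$pos, v3$ref, v3$alt, 1L))
  dip <- call_diplotype(vars, "CYP2C19", defs_kb)
  expect_true(dip$unexplained)
  ph <- assign_phenotype(dip, defs_kb)
  expect_equal(ph$phenotype, "indeterminate")
  expect_false(actionable_variant_flag(ph, guideline_kb))
})

test_that("diplotype calling matches the brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:40) {
    toy <- random_toy_defs()
    keys <- paste(toy$pool$chrom, toy$pool$pos, toy$pool$ref, toy$pool$alt)
    for (case in 1:4) {
      obs <- stats::setNames(sample(0:2, length(keys), replace = TRUE,
                                    prob = c(0.6, 0.25, 0.15)), keys)
      vars <- variants_from_dosage(obs, toy$pool)
      got <- call_diplotype(vars, "CYP2C19", toy$defs)
      want <- oracle_diplotype(obs, toy$defs)
      expect_equal(sort(c(got$allele_1, got$allele_2)),
                   sort(c(want$a, want$b)),
                   info = paste("obs:", paste(obs, collapse = ",")))
      # non-defining positions are outside the caller's remit; a call is
      # unexplained only when defining-position genotypes stay unmatched
      def_keys <- with(toy$defs$variants, paste(chrom, pos, ref, alt))
      expect_equal(got$unexplained,
                   want$score < sum(obs[names(obs) %in% def_keys] > 0))
    }
  }
})

test_that("function-pair phenotypes follow the fixed lookup", {
  expect_equal(toy_phenotype("CYP2C19", "*17", "*17")$phenotype, "UM")
  expect_equal(toy_phenotype("CYP2C19", "*1", "*17")$phenotype, "RM")
  expect_equal(toy_phenotype("CYP2C19", "*1", "*1")$phenotype, "NM")
  expect_equal(toy_phenotype("CYP2C19", "*1", "*2")$phenotype, "IM")
  expect_equal(toy_phenotype("CYP2C19", "*2", "*2")$phenotype, "PM")
  expect_equal(toy_phenotype("CYP2C19", "*17", "*2")$phenotype, "IM")
  # sub-allele suffix normalizes to the core allele for function lookup
  expect_equal(toy_phenotype("CYP2C19", "*2B", "*2B")$phenotype, "PM")
  # CYP3A5 expresser logic
  expect_equal(toy_phenotype("CYP3A5", "*1", "*3")$phenotype, "IM")
  expect_equal(toy_phenotype("CYP3A5", "*3", "*3")$phenotype, "PM")
})

test_that("activity-score genes sum and bin, keeping the CYP2C9 IM split", {
  p <- toy_phenotype("CYP2C9", "*1", "*1")
  expect_equal(p$phenotype, "NM")
  expect_equal(p$activity_score, 2)

  p <- toy_phenotype("CYP2C9", "*1", "*2")
  expect_equal(p$phenotype, "IM")
  expect_equal(p$activity_score, 1.5)
  expect_equal(p$guideline_label, "IM (AS 1.5)")

  p <- toy_phenotype("CYP2C9", "*1", "*3")
  expect_equal(p$phenotype, "IM")
  expect_equal(p$activity_score, 1.0)
  expect_equal(p$guideline_label, "IM (AS 1)")

  expect_equal(toy_phenotype("CYP2C9", "*3", "*3")$phenotype, "PM")
  expect_equal(toy_phenotype("CYP2C9", "*2", "*3")$phenotype, "PM")

  expect_equal(toy_phenotype("CYP2D6", "*1", "*2")$phenotype, "NM")
  expect_equal(toy_phenotype("CYP2D6", "*1", "*4")$phenotype, "IM")
  expect_equal(toy_phenotype("CYP2D6", "*4", "*4")$phenotype, "PM")
  expect_equal(toy_phenotype("CYP2D6", "*4", "*10")$phenotype, "IM")
})

test_that("transporter, X-linked and single-variant vocabularies map correctly", {
  expect_equal(toy_phenotype("SLCO1B1", "*1", "*5")$phenotype,
               "decreased function")
  expect_equal(toy_phenotype("SLCO1B1", "*5", "*5")$phenotype,
               "poor function")
  expect_equal(toy_phenotype("SLCO1B1", "*1", "*14")$phenotype,
               "increased function")

  # G6PD: hemizygous male vs heterozygous female
  expect_equal(toy_phenotype("G6PD", "A-", NA)$phenotype, "deficient")
  expect_equal(toy_phenotype("G6PD", "B", NA)$phenotype, "normal")
  expect_equal(toy_phenotype("G6PD", "B", "A-")$phenotype, "variable")
  expect_equal(toy_phenotype("G6PD", "A-", "Mediterranean")$phenotype,
               "deficient")

  expect_equal(toy_phenotype("VKORC1", "wildtype", "rs9923231")$phenotype,
               "rs9923231 heterozygous")
  expect_equal(toy_phenotype("ABCG2", "rs2231142", "rs2231142")$phenotype,
               "rs2231142 homozygous")
  expect_equal(toy_phenotype("ABCG2", "wildtype", "wildtype")$phenotype,
               "wildtype")
})

test_that("phenotype assignment is symmetric in allele order and idempotent", {
  pairs <- list(c("*1", "*17"), c("*2", "*17"), c("*1", "*2"))
  for (p in pairs) {
    a <- toy_phenotype("CYP2C19", p[1], p[2])
    b <- toy_phenotype("CYP2C19", p[2], p[1])
    expect_equal(a$phenotype, b$phenotype)
    expect_equal(a$actionable_variant, b$actionable_variant)
    expect_equal(toy_phenotype("CYP2C19", p[1], p[2])$phenotype, a$phenotype)
  }
})

test_that("actionable-variant policies treat normal phenotypes differently", {
  nm <- toy_phenotype("CYP2C19", "*1", "*1")
  expect_false(actionable_variant_flag(nm, guideline_kb, "default"))
  # pantoprazole recommends dosing even for CYP2C19 NM
  expect_true(actionable_variant_flag(nm, guideline_kb, "include_normal"))

  expect_false(actionable_variant_flag(toy_phenotype("NUDT15", "*1", "*1"),
                                       guideline_kb))
  expect_true(actionable_variant_flag(toy_phenotype("SLCO1B1", "*1", "*5"),
                                      guideline_kb))
  expect_true(toy_phenotype("CYP2C19", "*1", "*2")$actionable_variant)
  # VKORC1 heterozygotes have no actionable entry
  expect_false(toy_phenotype("VKORC1", "wildtype",
                             "rs9923231")$actionable_variant)
})
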