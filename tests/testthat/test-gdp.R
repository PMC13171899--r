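phen_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(individual_id = r[[1]], gene = r[[2]],
                   guideline_label = r[[3]])))
}

test_that("gene-drug pairs join drugs with every implicated gene", {
  meds <- tibble::tibble(individual_id = "P1", drug = "Amitriptyline",
                         source = "ongoing")
  phen <- phen_tbl(list("P1", "CYP2C19", "NM"), list("P1", "CYP2D6", "IM"))
  gdps <- build_gdps(meds, phen, guideline_kb)
  expect_equal(nrow(gdps), 2)
  expect_setequal(gdps$gene, c("CYP2C19", "CYP2D6"))
  # CYP2D6 IM amitriptyline is a dosing recommendation, hence actionable
  expect_true(gdps$actionable[gdps$gene == "CYP2D6"])
  expect_false(gdps$actionable[gdps$gene == "CYP2C19"])

  # pantoprazole CYP2C19 IM: dosing, actionable
  meds <- tibble::tibble(individual_id = "P2", drug = "pantoprazole")
  phen <- phen_tbl(list("P2", "CYP2C19", "IM"))
  gdps <- build_gdps(meds, phen, guideline_kb)
  expect_equal(gdps$recommendation, "dosing")
  expect_true(gdps$actionable)
})

test_that("uncovered drugs and missing phenotypes are reported, not paired", {
  meds <- tibble::tibble(individual_id = c("P1", "P1", "P1"),
                         drug = c("acetaminophen", "vitamin d", "tacrolimus"))
  phen <- phen_tbl(list("P1", "CYP2C19", "NM"))  # no CYP3A5 call
  gdps <- build_gdps(meds, phen, guideline_kb)
  expect_equal(nrow(gdps), 0)
  expect_setequal(attr(gdps, "uncovered_drugs"),
                  c("acetaminophen", "vitamin d"))
  expect_equal(attr(gdps, "skipped")$gene, "CYP3A5")
})

test_that("duplicate medication records do not duplicate pairs", {
  meds <- tibble::tibble(
    individual_id = "P1", drug = c("pantoprazole", "Pantoprazole"),
    source = c("prior_report", "ongoing"))
  phen <- phen_tbl(list("P1", "CYP2C19", "NM"))
  expect_equal(nrow(build_gdps(meds, phen, guideline_kb)), 1)
})

test_that("actionability follows the category rule with indeterminate excluded", {
  expect_false(classify_actionable("no_action"))
  expect_true(classify_actionable("dosing"))
  expect_true(classify_actionable("alternate_drug"))
  expect_true(classify_actionable("dosing_alternate_drug"))
  expect_false(classify_actionable("other", FALSE))
  expect_true(classify_actionable("other", TRUE))

  # metoprolol IM carries no action; atomoxetine is actionable even at NM;
  # risperidone indeterminate is never actionable
  meds <- tibble::tibble(individual_id = c("A", "B", "C"),
                         drug = c("metoprolol", "atomoxetine", "risperidone"))
  phen <- phen_tbl(list("A", "CYP2D6", "IM"), list("B", "CYP2D6", "NM"),
                   list("C", "CYP2D6", "indeterminate"))
  gdps <- build_gdps(meds, phen, guideline_kb)
  expect_equal(gdps$actionable[gdps$drug == "metoprolol"], FALSE)
  expect_equal(gdps$actionable[gdps$drug == "atomoxetine"], TRUE)
  expect_equal(gdps$actionable[gdps$drug == "risperidone"], FALSE)
})

test_that("the incidence-table fixture cohort reproduces the printed tallies", {
  tc <- incidence_cohort()
  gdps <- build_gdps(tc$meds, tc$phenotypes, guideline_kb)
  t1 <- reconstruct_incidence_table(gdps)

  expect_equal(t1$total_gdps, 406)
  expect_equal(t1$total_actionable, 153)

  want <- tibble::tribble(
    ~gene, ~n, ~n_actionable,
    "CYP2C19", 137L, 105L,
    "CYP2D6", 106L, 24L,
    "CYP2C9", 86L, 12L,
    "CYP2B6", 13L, 6L,
    "SLCO1B1", 26L, 6L,
    "ABCG2", 7L, 0L,
    "CYP3A5", 4L, 0L,
    "DPYD", 1L, 0L,
    "G6PD", 3L, 0L,
    "NUDT15", 11L, 0L,
    "TPMT", 11L, 0L,
    "VKORC1", 1L, 0L)
  got <- t1$by_gene[match(want$gene, t1$by_gene$gene), ]
  expect_equal(got$n, want$n)
  expect_equal(got$n_actionable, want$n_actionable)
  expect_equal(got$pct_actionable[got$gene == "CYP2C19"], 76.6, tolerance = 1e-3)

  bd <- t1$by_drug
  expect_equal(bd$n_actionable[bd$drug == "pantoprazole" &
                               bd$gene == "CYP2C19"], 77L)
  expect_equal(bd$n_actionable[bd$drug == "ibuprofen"], 11L)
  expect_equal(bd$n_actionable[bd$drug == "omeprazole"], 10L)
  expect_equal(bd$n_actionable[bd$drug == "amitriptyline" &
                               bd$gene == "CYP2D6"], 5L)
  zero_genes <- t1$by_gene$gene[t1$by_gene$n_actionable == 0]
  expect_setequal(zero_genes,
                  c("ABCG2", "DPYD", "G6PD", "NUDT15", "TPMT", "CYP3A5",
                    "VKORC1"))

  # conservation: per-drug sums equal per-gene totals equal grand total
  expect_equal(sum(bd$n), t1$total_gdps)
  agg <- stats::aggregate(n ~ gene, data = as.data.frame(bd), sum)
  expect_equal(agg$n[order(agg$gene)],
               t1$by_gene$n[order(t1$by_gene$gene)])
})

test_that("single-individual roll-up equals that individual's rows", {
  meds <- tibble::tibble(individual_id = "P1",
                         drug = c("pantoprazole", "ibuprofen"))
  phen <- phen_tbl(list("P1", "CYP2C19", "IM"), list("P1", "CYP2C9", "NM"))
  gdps <- build_gdps(meds, phen, guideline_kb)
  t1 <- reconstruct_incidence_table(gdps)
  expect_equal(t1$total_gdps, nrow(gdps))
  expect_equal(sum(t1$cells$n), nrow(gdps))
})

test_that("carrier frequencies report both conventions", {
  ev <- tibble::tibble(gene = "CYP2C19", kind = "deletion", n_carriers = 7)
  f <- event_frequencies(ev, 1000)
  expect_equal(f$carrier_pct, 0.7)
  expect_equal(f$allele_pct, 0.35)

  f <- event_frequencies(tibble::tibble(n_carriers = 0), 1000)
  expect_equal(f$carrier_pct, 0)
  expect_equal(f$allele_pct, 0)

  f <- event_frequencies(tibble::tibble(n_carriers = 5), 650)
  expect_equal(round(f$carrier_pct, 2), 0.77)
})

test_that("flipping a no_action entry to dosing never lowers actionable tallies", {
  tc <- incidence_cohort()
  base <- reconstruct_incidence_table(build_gdps(tc$meds, tc$phenotypes, guideline_kb))
  edited <- guideline_kb
  flip <- which(edited$entries$recommendation == "no_action")[
    c(1, 5, 10, 20)]
  edited$entries$recommendation[flip] <- "dosing"
  edited$entries$actionable[flip] <- TRUE
  after <- reconstruct_incidence_table(build_gdps(tc$meds, tc$phenotypes, edited))
  expect_gte(after$total_actionable, base$total_actionable)
  merged <- merge(as.data.frame(base$by_gene), as.data.frame(after$by_gene),
                  by = "gene")
  expect_true(all(merged$n_actionable.y >= merged$n_actionable.x))
})

test_that("cohort summary statistics aggregate deterministically", {
  tc <- incidence_cohort()
  gdps <- build_gdps(tc$meds, tc$phenotypes, guideline_kb)
  s <- summarize_cohort(gdps, n_individuals = nrow(tc$phenotypes),
                        n_with_medication_data = 359)
  expect_equal(s$gdp_count, 406)
  expect_equal(s$actionable_gdp_count, 153)
  expect_lte(s$actionable_gdp_count, s$gdp_count)

  # empty medication table: all tallies zero
  empty <- build_gdps(tibble::tibble(individual_id = character(0),
                                     drug = character(0)),
                      tc$phenotypes, guideline_kb)
  s0 <- summarize_cohort(empty, n_with_medication_data = 0)
  expect_equal(s0$gdp_count, 0)
  expect_equal(s0$actionable_gdp_count, 0)
  expect_equal(s0$mean_gdps_per_individual, 0)
})
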