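# Two-variant panel classification, distribution table and yields.

test_that("panel category assignment matches the published row structure", {
  expect_identical(panel_category(2L, 0L, 0L), "homA")
  expect_identical(panel_category(0L, 2L, 0L), "homB")
  expect_identical(panel_category(1L, 1L, 0L), "compound_AB")
  expect_identical(panel_category(1L, 0L, 1L), "hetA_plus_other")
  expect_identical(panel_category(0L, 1L, 2L), "hetB_plus_other")
  expect_identical(panel_category(1L, 0L, 0L), "hetA_only")
  expect_identical(panel_category(0L, 1L, 0L), "hetB_only")
  expect_identical(panel_category(0L, 0L, 2L), "others_only")
  expect_identical(panel_category(0L, 0L, 1L), "none")  # one other allele
  expect_identical(panel_category(0L, 0L, 0L), "none")
})

test_that("every count combination lands in exactly one category", {
  grid <- expand.grid(a = 0:2, b = 0:2, o = 0:4)
  cat <- panel_category(grid$a, grid$b, grid$o)
  expect_true(all(cat %in% c("homA", "homB", "compound_AB", "hetA_plus_other",
                             "hetB_plus_other", "hetA_only", "hetB_only",
                             "others_only", "none")))
  expect_identical(length(cat), nrow(grid))
})

test_that("classify_panel counts panel and other alleles from genotypes", {
  d <- make_paper_cohort("discovery")
  cas <- run_cascade(d)
  cls <- classify_panel(d, qualifying_variants = cas$surviving_variants,
                        mode = "wes")
  expect_identical(nrow(cls), 31L)
  expect_identical(sum(cls$category == "homA"), 10L)
  expect_identical(sum(cls$category == "compound_AB"), 7L)
  expect_identical(sum(cls$category == "others_only"), 3L)
  # decoy calls (common/synonymous/in-house) never count as "others"
  expect_true(all(cls$other_alleles <= 2L))
})

test_that("genotyping-only mode reports others as unknown", {
  r <- make_paper_cohort("replication")
  cls <- classify_panel(r, mode = "genotyping")
  expect_true(all(!cls$others_known))
  expect_true(all(cls$other_alleles == 0L))
  expect_false("others_only" %in% cls$category)
})

test_that("a panel variant absent from the cohort is a named hard error", {
  r <- make_paper_cohort("replication")
  pan <- panel_definition()
  pan$pos[2] <- 999L
  expect_error(classify_panel(r, panel_definition(as.data.frame(pan)),
                              mode = "genotyping"),
               "p.Arg90His", fixed = TRUE)
})

test_that("tabulate_distribution matches a brute-force recount", {
  for (seed in c(2, 9, 44)) {
    cls <- rand_classifications(120, seed)
    s <- tabulate_distribution(cls)
    expect_identical(sum(s$counts), nrow(cls))
    for (lev in names(s$counts))
      expect_identical(s$counts[[lev]], sum(cls$category == lev))
    # percent strings reconstruct count/denominator to rounding tolerance
    pct <- as.numeric(sub("%", "", s$percents))
    expect_true(all(abs(pct - 100 * s$counts / s$n) <= 0.05 + 1e-9))
    # roll-up partitions the cohort
    expect_identical(sum(s$rollup$count), nrow(cls))
  }
  expect_error(tabulate_distribution(rand_classifications(5, 1)[0, ]), "empty")
})

test_that("screening yield equals the brute-force indicator sum", {
  for (seed in c(3, 12)) {
    cls <- rand_classifications(80, seed)
    y <- screening_yield(cls)
    oracle <- sum(cls$alleles_A + cls$alleles_B >= 1)
    expect_identical(y$numerator, oracle)
    expect_equal(y$proportion, oracle / 80)
  }
  none <- rand_classifications(10, 7)
  none$alleles_A <- none$alleles_B <- 0L
  none$other_alleles <- 0L
  none$category <- panel_category(none$alleles_A, none$alleles_B,
                                  none$other_alleles)
  expect_identical(screening_yield(none)$fraction, "0/10")
})

test_that("published two-variant yields reproduce, single hets labelled", {
  d <- make_paper_cohort("discovery")
  casd <- run_cascade(d)
  clsd <- classify_panel(d, qualifying_variants = casd$surviving_variants,
                         mode = "wes")
  expect_identical(screening_yield(clsd)$fraction, "24/31")
  r <- make_paper_cohort("replication")
  clsr <- classify_panel(r, mode = "genotyping")
  yr <- screening_yield(clsr)
  expect_identical(yr$fraction, "47/50")
  expect_identical(yr$percent, "94.0%")
  expect_identical(yr$n_single_het, 14L)  # the permissive screening margin
  yc <- screening_yield(rbind(clsd, clsr))
  expect_identical(yc$fraction, "71/81")
  expect_identical(yc$percent, "87.7%")
})

test_that("bi-allelic yield counts cascade diagnoses for the panel gene", {
  d <- make_paper_cohort("discovery")
  cas <- run_cascade(d)
  expect_identical(biallelic_yield(cas$diagnoses, "SLC22A12")$fraction,
                   "27/31")
  expect_identical(biallelic_yield(cas$diagnoses, "SLC2A9")$numerator, 1L)
  expect_error(biallelic_yield(cas$diagnoses[0, ], "SLC22A12"), "empty")
})

test_that("screen-positive set contains all panel-allele diagnoses", {
  sim <- simulate_cohort(enriched_config(2500, seed = 19))
  cas <- run_cascade(sim$cohort)
  cls <- classify_panel(sim$cohort, qualifying_variants =
                          cas$surviving_variants, mode = "wes")
  pv <- panel_definition()
  uses_panel <- vapply(seq_len(nrow(cas$diagnoses)), function(i)
    cas$diagnoses$zygosity_class[i] != "none" &&
      any(cas$diagnoses$qualifying[[i]]$variant_key %in% pv$variant_key),
    logical(1))
  pos <- cls$individual_id[cls$alleles_A + cls$alleles_B >= 1]
  expect_true(all(cas$diagnoses$individual_id[uses_panel] %in% pos))
})

test_that("computed percents are reported and published typos flagged", {
  pub <- published_distribution()$replication
  counts <- stats::setNames(pub$count, pub$category)
  cmp <- compare_percent_strings(counts, 50,
                                 stats::setNames(pub$published_pct,
                                                 pub$category))
  expect_identical(cmp$computed[cmp$name == "none"], "6.0%")
  expect_true(cmp$mismatch[cmp$name == "none"])  # published prints 6.6%
  expect_false(any(cmp$mismatch[cmp$name != "none"]))
})
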