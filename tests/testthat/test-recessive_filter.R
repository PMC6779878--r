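# The four-step recessive filtering cascade.

test_that("frequency filter removes common variants, keeps unobserved ones", {
  v <- variant_table(
    chrom = "1", pos = 1:4 * 10L, ref = "A", alt = "G", gene = "G1",
    consequence = "missense",
    freqs = data.frame(af_gnomad = c(0.05, 0.000044, NA, 0.009),
                       af_1kg = c(NA, NA, NA, 0.02)))
  out <- filter_by_maf(v, filter_config())
  expect_setequal(out$pos, c(20L, 30L))  # 0.05 and the 2% af_1kg removed
  # absence of frequency evidence in every source survives
  expect_true(30L %in% out$pos)
})

test_that("frequency filter equals the per-source brute-force oracle", {
  set.seed(77)
  n <- 200
  af <- matrix(stats::runif(n * 3, 0, 0.05), n, 3)
  af[stats::runif(n * 3) < 0.4] <- NA
  v <- variant_table(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                     gene = "G1", consequence = "missense",
                     freqs = stats::setNames(as.data.frame(af),
                                             c("af_a", "af_b", "af_c")))
  for (thr in c(0.001, 0.01, 0.03)) {
    cfg <- filter_config(maf_threshold = thr)
    got <- filter_by_maf(v, cfg)$variant_key
    oracle <- v$variant_key[vapply(seq_len(n), function(i) {
      fs <- af[i, ][!is.na(af[i, ])]
      length(fs) == 0 || max(fs) <= thr
    }, logical(1))]
    expect_identical(got, oracle)
    # the two aggregation policies coincide for scalar sources
    expect_identical(
      filter_by_maf(v, filter_config(thr, maf_policy = "max_across_sources")),
      filter_by_maf(v, cfg))
  }
})

test_that("in-house filter removes hom/hemi control hits only, idempotently", {
  v <- variant_table(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G",
                     gene = "G1", consequence = "missense",
                     inhouse_hom = c(TRUE, FALSE))
  out <- filter_inhouse(v)
  expect_identical(out$pos, 20L)  # het-only control presence is not modelled
                                  # as inhouse_hom, so pos 20 is retained
  expect_identical(filter_inhouse(out), out)
})

test_that("consequence filter equals the set-membership oracle", {
  set.seed(5)
  cons <- sample(consequence_levels(), 100, replace = TRUE)
  v <- variant_table(chrom = "1", pos = 1:100, ref = "A", alt = "G",
                     gene = "G1", consequence = cons)
  cfg <- filter_config()
  out <- filter_consequence(v, cfg)
  expect_identical(out$variant_key,
                   v$variant_key[cons %in% cfg$consequence_keep])
  expect_false(any(out$consequence %in% c("synonymous", "other")))
  expect_true("stop_gained" %in% out$consequence)
})

test_that("variant-level steps are idempotent and order-commutative", {
  sim <- simulate_cohort(enriched_config(300, seed = 17))
  v <- sim$cohort$variants
  cfg <- filter_config()
  s1 <- function(x) filter_by_maf(x, cfg)
  s2 <- filter_inhouse
  s3 <- function(x) filter_consequence(x, cfg)
  ref <- s3(s2(s1(v)))
  expect_identical(s1(s3(s2(v)))$variant_key, ref$variant_key)
  expect_identical(s2(s1(s3(v)))$variant_key, ref$variant_key)
  expect_identical(s1(s1(v)), s1(v))
})

test_that("bi-allelic collection assigns zygosity classes", {
  co <- tiny_cohort()
  v <- filter_consequence(co$variants, filter_config())
  d1 <- collect_biallelic(co$individuals[1, ], co$genotypes, v)
  expect_identical(d1$zygosity_class, "homozygous")
  expect_identical(d1$gene, "SLC22A12")
  expect_true(d1$phase_resolved)
  d2 <- collect_biallelic(co$individuals[2, ], co$genotypes, v)
  expect_identical(d2$zygosity_class, "compound_het")
  expect_false(d2$phase_resolved)
  # male with one X allele -> hemizygous
  d3 <- collect_biallelic(co$individuals[3, ], co$genotypes, v)
  expect_identical(d3$zygosity_class, "hemizygous")
  expect_identical(d3$gene, "XGENE")
  # single autosomal het -> none
  d4 <- collect_biallelic(co$individuals[4, ], co$genotypes, v)
  expect_identical(d4$zygosity_class, "none")
  expect_identical(d4$n_qualifying_alleles, 0L)
})

test_that("female X single het is not hemizygous; hom dominates extra hets", {
  v <- variant_table(chrom = c("X", "11", "11"), pos = c(5L, 6L, 7L),
                     ref = "A", alt = "G", gene = c("XG", "AG", "AG"),
                     consequence = "missense")
  ind <- individual_table(c("F1", "M1"), c("female", "male"), c(1, 1))
  g <- genotype_table(c("F1", "M1", "M1"),
                      v$variant_key[c(1, 2, 3)], c(1L, 2L, 1L),
                      hemizygous = FALSE)
  co <- rhuc_cohort(ind, g, v)
  df <- collect_biallelic(co$individuals[co$individuals$individual_id == "F1", ],
                          co$genotypes, v)
  expect_identical(df$zygosity_class, "none")
  dm <- collect_biallelic(co$individuals[co$individuals$individual_id == "M1", ],
                          co$genotypes, v)
  expect_identical(dm$zygosity_class, "homozygous")  # hom + extra het
  expect_identical(dm$n_qualifying_alleles, 3L)
})

test_that("multi-gene qualification reports all genes, ranked", {
  v <- variant_table(chrom = "1", pos = c(1L, 2L, 3L, 4L), ref = "A",
                     alt = "G", gene = c("BBB", "BBB", "AAA", "AAA"),
                     consequence = "missense",
                     known_pathogenic = c(TRUE, TRUE, FALSE, FALSE))
  ind <- individual_table("I1", "female", 1)
  g <- genotype_table(rep("I1", 4), v$variant_key, rep(1L, 4))
  d <- collect_biallelic(ind, g, v)
  expect_identical(d$genes, "AAA,BBB")
  # previously-reported majority outranks lexicographic order
  expect_identical(d$gene, "BBB")
})

test_that("cascade survival counts are non-increasing and logged", {
  sim <- simulate_cohort(enriched_config(500, seed = 23))
  cas <- run_cascade(sim$cohort)
  expect_true(all(diff(cas$step_counts) <= 0))
  expect_named(cas$step_counts,
               c("input", "maf", "inhouse", "consequence", "biallelic"))
  # empty variant collection -> every diagnosis none
  empty <- rhuc_cohort(sim$cohort$individuals, genotype_table(),
                       sim$cohort$variants[0, , drop = FALSE])
  cas0 <- run_cascade(empty)
  expect_true(all(cas0$diagnoses$zygosity_class == "none"))
})

test_that("lowering maf_threshold never increases survivors", {
  sim <- simulate_cohort(enriched_config(200, seed = 31))
  ns <- vapply(c(0.2, 0.05, 0.01, 0.001, 1e-5), function(thr)
    nrow(filter_by_maf(sim$cohort$variants, filter_config(thr))), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("no individual with at most one allele per gene is diagnosed", {
  for (seed in 1:5) {
    sim <- simulate_cohort(enriched_config(400, seed = seed))
    cas <- run_cascade(sim$cohort)
    v3 <- cas$surviving_variants
    g <- sim$cohort$genotypes[sim$cohort$genotypes$variant_key %in%
                                v3$variant_key, , drop = FALSE]
    g$gene <- v3$gene[match(g$variant_key, v3$variant_key)]
    per_gene <- stats::aggregate(alt_count ~ individual_id + gene, g, sum)
    max_alleles <- tapply(per_gene$alt_count, per_gene$individual_id, max)
    sex <- sim$cohort$individuals$sex[
      match(names(max_alleles), sim$cohort$individuals$individual_id)]
    chrx <- v3$chrom %in% c("X", "chrX")
    # autosomal-only carriers with <= 1 allele in every gene: never diagnosed
    singles <- names(max_alleles)[max_alleles <= 1 & sex == "female"]
    diag <- cas$diagnoses
    expect_true(all(diag$zygosity_class[diag$individual_id %in% singles] ==
                      "none"))
  }
})

test_that("cascade recovers the simulation truth exactly when transient-free", {
  sim <- simulate_cohort(enriched_config(2000, seed = 41))
  cas <- run_cascade(sim$cohort)
  diagnosed <- cas$diagnoses$individual_id[cas$diagnoses$zygosity_class !=
                                             "none"]
  expect_setequal(diagnosed,
                  sim$truth$id[sim$truth$class == "biallelic_carrier"])
  # diagnosed gene matches the generative causal gene
  hit <- cas$diagnoses[cas$diagnoses$zygosity_class != "none", ]
  expect_identical(hit$gene,
                   sim$truth$causal_gene[match(hit$individual_id,
                                               sim$truth$id)])
})

test_that("discovery worked example reproduces the published cascade yield", {
  d <- make_paper_cohort("discovery")
  cas <- run_cascade(d)
  by <- biallelic_yield(cas$diagnoses, "SLC22A12")
  expect_identical(by$fraction, "27/31")
  expect_identical(by$percent, "87.1%")
})
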