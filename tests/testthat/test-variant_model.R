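# Domain types and VCF/TSV round-tripping.

test_that("variant and individual constructors enforce their invariants", {
  expect_error(variant_table("1", 0L, "A", "G", "G1", "missense"), "positions")
  expect_error(variant_table("1", 5L, "A", "A", "G1", "missense"), "differ")
  expect_error(variant_table("1", 5L, "A", "G", "G1", "nonsense_class"),
               "consequence")
  expect_error(variant_table("1", 5L, "A", "G", "G1", "missense",
                             freqs = data.frame(af_x = 1.2)), "\\[0,1\\]")
  expect_error(individual_table("A", "unknown", 1), "male")
  expect_error(individual_table("A", "male", -1), "non-negative")
  expect_error(individual_table("A", "male", 1, flags = "glaucoma"), "flag")
  expect_error(genotype_table("A", "k", 3L), "alt_count")
  expect_error(genotype_table("A", "k", 2L, hemizygous = TRUE), "hemizygous")
})

test_that("cohort assembly checks referential integrity and hemizygosity", {
  co <- tiny_cohort()
  expect_s3_class(co, "rhuc_cohort")
  bad_g <- genotype_table("I1", "nope:1:A:G", 1L)
  expect_error(rhuc_cohort(co$individuals, bad_g, co$variants),
               "unknown variant_key")
  # male X call must be flagged hemizygous
  k5 <- co$variants$variant_key[co$variants$gene == "XGENE"]
  g <- genotype_table("I3", k5, 1L, hemizygous = FALSE)
  expect_error(rhuc_cohort(co$individuals, g, co$variants), "hemizygous")
})

test_that("single het call round-trips through the VCF dialect", {
  co <- tiny_cohort()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  phe <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, vcf, phe)
  txt <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", txt)))
  # I1 is hom for the first variant -> "1/1"; I2 het -> "0/1"
  row1 <- strsplit(grep("^11\t100", txt, value = TRUE), "\t")[[1]]
  hdr <- strsplit(grep("^#CHROM", txt, value = TRUE), "\t")[[1]]
  expect_identical(row1[hdr == "I1"], "1/1")
  expect_identical(row1[hdr == "I2"], "0/1")
  # male X call is written haploid
  rowx <- strsplit(grep("^X\t900", txt, value = TRUE), "\t")[[1]]
  expect_identical(rowx[hdr == "I3"], "1")
  expect_identical(rowx[hdr == "I2"], "0")
  co2 <- read_cohort(vcf, phe)
  expect_identical(co2, co)
})

test_that("simulated fixture round-trips bit-identically through write+read", {
  sim <- simulate_cohort(enriched_config(200, seed = 5))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  phe <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(sim$cohort, vcf, phe)
  co2 <- read_cohort(vcf, phe)
  expect_identical(co2, sim$cohort)
  # write(read(x)) is byte-identical to write(x)
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  phe2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co2, vcf2, phe2)
  expect_identical(readLines(vcf2), readLines(vcf))
  expect_identical(readLines(phe2), readLines(phe))
})

test_that("empty cohort writes a valid header-only VCF", {
  co <- rhuc_cohort(individual_table(character(0), character(0), numeric(0)),
                    genotype_table(),
                    tiny_variants()[0, , drop = FALSE])
  vcf <- withr::local_tempfile(fileext = ".vcf")
  phe <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, vcf, phe)
  txt <- readLines(vcf)
  expect_true(all(grepl("^#", txt)))
  co2 <- read_cohort(vcf, phe)
  expect_identical(nrow(co2$individuals), 0L)
  expect_identical(nrow(co2$variants), 0L)
})

test_that("multi-allelic records split per alt and conserve allele totals", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  phe <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=11>",
    '##INFO=<ID=GENE,Number=A,Type=String,Description="g">',
    '##INFO=<ID=CSQ,Number=A,Type=String,Description="c">',
    '##INFO=<ID=AF_gnomad,Number=A,Type=Float,Description="af">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("11", "500", ".", "G", "A,T", ".", ".",
          "GENE=SLC22A12,SLC22A12;CSQ=missense,stop_gained;AF_gnomad=0.001,0.002",
          "GT", "1/2", "0/1", sep = "\t")), vcf)
  writeLines(c("id\tsex\tua\tflags", "S1\tmale\t0.9\t", "S2\tfemale\t4.2\t"),
             phe)
  co <- read_cohort(vcf, phe)
  expect_identical(nrow(co$variants), 2L)
  expect_setequal(co$variants$alt, c("A", "T"))
  expect_identical(co$variants$consequence[co$variants$alt == "T"],
                   "stop_gained")
  # per-site alt-allele total conserved across the split: S1 carries one A
  # and one T, S2 one A -> 3 alt alleles in total
  expect_identical(sum(co$genotypes$alt_count), 3L)
  expect_identical(
    co$genotypes$alt_count[co$genotypes$individual_id == "S1"], c(1L, 1L))
})

test_that("sample-set mismatch is a hard error listing the difference", {
  co <- tiny_cohort()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  phe <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, vcf, phe)
  short <- co$individuals[co$individuals$individual_id != "I4", , drop = FALSE]
  phe2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype(short, phe2)
  expect_error(read_cohort(vcf, phe2), "I4")
})

test_that("unparseable consequence degrades to 'other' with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  phe <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##INFO=<ID=GENE,Number=A,Type=String,Description="g">',
    '##INFO=<ID=CSQ,Number=A,Type=String,Description="c">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "10", ".", "A", "G", ".", ".", "GENE=G1;CSQ=weird_thing",
          "GT", "0/1", sep = "\t")), vcf)
  writeLines(c("id\tsex\tua\tflags", "S1\tmale\t3.0\t"), phe)
  expect_warning(co <- read_cohort(vcf, phe), "weird_thing")
  expect_identical(co$variants$consequence, "other")
})
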