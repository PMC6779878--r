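# Handmade fixtures shared across test files. Everything is built in code;
# no binary data.

tiny_variants <- function() {
  variant_table(
    chrom = c("11", "11", "11", "4", "X"),
    pos = c(100L, 200L, 300L, 50L, 900L),
    ref = c("G", "C", "A", "G", "T"),
    alt = c("A", "T", "G", "A", "C"),
    gene = c("SLC22A12", "SLC22A12", "SLC22A12", "SLC2A9", "XGENE"),
    consequence = c("stop_gained", "missense", "synonymous", "missense",
                    "missense"),
    protein_change = c("p.Trp258*", "p.Arg90His", "p.Gly100Gly", "p.Arg198Cys",
                       "p.Val5Met"),
    freqs = data.frame(af_gnomad = c(0.001, 0.0002, NA, 0.00006, 0.004),
                       af_1kg = c(0.002, NA, NA, NA, NA)),
    inhouse_hom = FALSE,
    known_pathogenic = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
}

tiny_cohort <- function() {
  v <- tiny_variants()
  k <- v$variant_key
  ind <- individual_table(
    c("I1", "I2", "I3", "I4"),
    sex = c("female", "male", "male", "female"),
    serum_ua = c(0.8, 1.1, 5.4, 1.3),
    flags = c("", "", "hypertension", "")
  )
  g <- genotype_table(
    individual_id = c("I1", "I2", "I2", "I3", "I4"),
    variant_key = c(k[1], k[1], k[2], k[5], k[2]),
    alt_count = c(2L, 1L, 1L, 1L, 1L),
    hemizygous = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  rhuc_cohort(ind, g, v)
}

# random classification table for counting-oracle tests
rand_classifications <- function(n, seed) {
  set.seed(seed)
  a <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  b <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.25, 0.05))
  b[a == 2 & b == 2] <- 0  # four panel alleles in one subject is not a state
  o <- sample(0:3, n, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
  data.frame(individual_id = sprintf("P%03d", seq_len(n)),
             alleles_A = a, alleles_B = b, other_alleles = o,
             others_known = TRUE, category = panel_category(a, b, o),
             stringsAsFactors = FALSE)
}

# simulation settings with enriched founder alleles and well-separated
# urate classes, used by recovery and property tests
enriched_config <- function(n, seed, ...) {
  simulation_config(
    n, seed = seed,
    panel_freqs = c(trp258_stop = 0.05, arg90_his = 0.02),
    other_pathogenic_freq = 0.01, other_gene_fraction = 0.1,
    ua_params = list(biallelic_carrier = c(mean = 0.77, sd = 0.25),
                     single_het = c(mean = 4.0, sd = 0.5),
                     noncarrier = c(mean = 5.5, sd = 0.5)),
    transient_rate = 0, ...)
}
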