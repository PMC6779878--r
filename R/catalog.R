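# Built-in variant catalogue for URAT1-driven renal hypouricemia.
#
# Coordinates are GRCh37 chr11 for SLC22A12; cDNA labels follow
# NM_144585.2. The two founder alleles (p.Trp258*, p.Arg90His) are the
# screening panel; the remaining entries are the rarer pathogenic alleles
# seen in Korean hypouricemia cohorts. Allele-frequency values for the four
# novel alleles are the published database lookups; the others are
# illustrative sub-1% values. Positions marked approximate are placeholders
# consistent with exon order — the pipeline only uses them as opaque keys.

founder_panel_rows <- function() {
  data.frame(
    gene = "SLC22A12",
    cdna = c("c.774G>A", "c.269G>A"),
    protein = c("p.Trp258*", "p.Arg90His"),
    rsid = c("rs121907892", "rs121907896"),
    chrom = "11",
    pos = c(64361219L, 64359052L),
    ref = "G", alt = "A",
    stringsAsFactors = FALSE
  )
}

# All pathogenic SLC22A12 alleles the built-in cohorts may carry.
slc22a12_pathogenic_catalog <- function() {
  variant_table(
    chrom = rep("11", 10),
    pos = c(64361219L, 64359052L,  # founders: Trp258*, Arg90His
            64360256L,             # Asn136Lys
            64361095L,             # Thr217Met (approx)
            64361119L,             # Thr225Lys
            64366008L,             # Arg284Gln
            64367050L,             # Gln382Leu (approx)
            64367330L,             # Leu418Arg (approx)
            64367362L,             # Glu429Lys
            64368070L),            # Arg477His (approx)
    ref = c("G", "G", "C", "C", "C", "G", "A", "T", "G", "G"),
    alt = c("A", "A", "A", "T", "A", "A", "T", "G", "A", "A"),
    gene = "SLC22A12",
    consequence = c("stop_gained", rep("missense", 9)),
    protein_change = c("p.Trp258*", "p.Arg90His", "p.Asn136Lys", "p.Thr217Met",
                       "p.Thr225Lys", "p.Arg284Gln", "p.Gln382Leu",
                       "p.Leu418Arg", "p.Glu429Lys", "p.Arg477His"),
    cdna_change = c("c.774G>A", "c.269G>A", "c.408C>A", "c.650C>T", "c.674C>A",
                    "c.851G>A", "c.1145A>T", "c.1253T>G", "c.1285G>A",
                    "c.1430G>A"),
    freqs = data.frame(
      af_gnomad = c(0.00096, 0.00017, 0.000004, 0.00012, NA, 0.000019,
                    0.00002, 0.00007, 0.000044, 0.00009),
      af_exac   = c(0.0011, NA, NA, NA, NA, NA, NA, NA, 0.00005, NA),
      af_1kg    = c(0.0026, NA, NA, NA, NA, NA, NA, NA, NA, NA)
    ),
    inhouse_hom = FALSE,
    # the four novel missense alleles carry no prior pathogenicity report
    known_pathogenic = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE,
                         FALSE, TRUE)
  )
}

# Pathogenic SLC2A9 pair for RHUC type 2 carriers.
slc2a9_pathogenic_catalog <- function() {
  variant_table(
    chrom = "4", pos = c(9921900L, 10024800L), ref = c("C", "G"),
    alt = c("T", "A"), gene = "SLC2A9", consequence = "missense",
    protein_change = c("p.Arg198Cys", "p.Arg380Trp"),
    cdna_change = c("c.592C>T", "c.1138G>A"),
    freqs = data.frame(af_gnomad = c(0.00006, 0.00004)),
    known_pathogenic = TRUE
  )
}

# Non-qualifying decoys exercising the frequency, in-house and consequence
# filters: a common missense, a rare synonymous change and a rare missense
# seen homozygous in the in-house controls.
decoy_filter_catalog <- function() {
  variant_table(
    chrom = c("11", "11", "11"),
    pos = c(64365500L, 64366900L, 64360900L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    gene = "SLC22A12",
    consequence = c("missense", "synonymous", "missense"),
    protein_change = c("p.Ile163Val", "p.Gly334Gly", "p.Val211Met"),
    cdna_change = c("c.487A>G", "c.1002C>T", "c.631G>A"),
    freqs = data.frame(af_gnomad = c(0.15, 0.0005, 0.003),
                       af_1kg = c(0.18, NA, NA)),
    inhouse_hom = c(FALSE, FALSE, TRUE),
    known_pathogenic = FALSE
  )
}

lookup_by_protein <- function(variants, protein) {
  i <- match(protein, variants$protein_change)
  if (anyNA(i)) stopf("no catalogue entry for %s", paste(protein[is.na(i)],
                                                         collapse = ", "))
  variants$variant_key[i]
}

#' Deterministic worked-example cohorts
#'
#' Reconstructs, individual by individual, the two published Korean
#' hypouricemia cohorts from their reported *SLC22A12* allele
#' configurations: `"discovery"` gives the 31 exome-sequenced subjects
#' (10 hom p.Trp258*, 7 compound p.Trp258*/p.Arg90His, 2 hom p.Arg90His,
#' 5 p.Trp258* + one rarer allele, 3 with two rarer alleles, 4 without
#' qualifying *SLC22A12* variants), `"replication"` the 50 subjects typed
#' only at the two founder sites (10/22/1 bi-allelic, 10+4 single
#' heterozygotes, 3 negative). Serum urate values are deterministic values
#' below the 1.3 mg/dL case threshold; no randomness is involved.
#'
#' The four subjects without a *SLC22A12* genotype in the discovery cohort
#' carry a bi-allelic *SLC2A9* genotype (one subject) or bi-allelic
#' genotypes in synthetic placeholder candidate genes (`CAND1`–`CAND3`).
#'
#' @param cohort_name `"discovery"` or `"replication"`.
#' @return An `rhuc_cohort`.
#' @export
make_paper_cohort <- function(cohort_name = c("discovery", "replication")) {
  cohort_name <- match.arg(cohort_name)
  if (cohort_name == "replication") return(make_replication_cohort())

  v22 <- slc22a12_pathogenic_catalog()
  v29 <- slc2a9_pathogenic_catalog()
  vc <- variant_table(
    chrom = c("2", "7", "12"), pos = c(55031000L, 100200400L, 6644100L),
    ref = c("G", "C", "T"), alt = c("A", "T", "C"),
    gene = c("CAND1", "CAND2", "CAND3"), consequence = "missense",
    protein_change = c("p.Ala101Thr", "p.Pro88Leu", "p.Phe301Ser"),
    cdna_change = c("c.301G>A", "c.263C>T", "c.902T>C"),
    freqs = data.frame(af_gnomad = c(0.0001, NA, 0.00003), af_exac = NA_real_,
                       af_1kg = NA_real_),
    known_pathogenic = FALSE
  )
  variants <- rbind(fill_af_cols(v22), fill_af_cols(v29), fill_af_cols(vc),
                    fill_af_cols(decoy_filter_catalog()))

  key <- function(p) lookup_by_protein(variants, p)
  A <- key("p.Trp258*"); B <- key("p.Arg90His")

  ids <- sprintf("D%02d", 1:31)
  geno <- list()
  add <- function(id, keys, counts) {
    geno[[length(geno) + 1L]] <<- data.frame(
      individual_id = id, variant_key = keys, alt_count = as.integer(counts),
      hemizygous = FALSE, stringsAsFactors = FALSE)
  }
  # 10 hom Trp258* | 7 compound Trp258*/Arg90His | 2 hom Arg90His
  for (i in 1:10) add(ids[i], A, 2L)
  for (i in 11:17) add(ids[i], c(A, B), c(1L, 1L))
  for (i in 18:19) add(ids[i], B, 2L)
  # 5 with one Trp258* plus one rarer qualifying allele
  others_het <- c("p.Glu429Lys", "p.Thr217Met", "p.Gln382Leu", "p.Arg477His",
                  "p.Leu418Arg")
  for (i in 20:24) add(ids[i], c(A, key(others_het[i - 19L])), c(1L, 1L))
  # 3 with two rarer alleles (all compound heterozygous)
  add(ids[25], key(c("p.Thr225Lys", "p.Arg284Gln")), c(1L, 1L))
  add(ids[26], key(c("p.Asn136Lys", "p.Leu418Arg")), c(1L, 1L))
  add(ids[27], key(c("p.Thr217Met", "p.Gln382Leu")), c(1L, 1L))
  # 4 without qualifying SLC22A12 variants
  add(ids[28], lookup_by_protein(variants, c("p.Arg198Cys", "p.Arg380Trp")),
      c(1L, 1L))
  add(ids[29], key("p.Ala101Thr"), 2L)
  add(ids[30], key("p.Pro88Leu"), 2L)
  add(ids[31], key("p.Phe301Ser"), 2L)
  # decoy carrier calls (filtered out by the cascade)
  add(ids[1], key("p.Ile163Val"), 1L)
  add(ids[2], key("p.Ile163Val"), 2L)
  add(ids[3], key("p.Gly334Gly"), 1L)
  add(ids[4], key("p.Val211Met"), 1L)

  sex <- rep("female", 31)
  sex[seq(1, 31, by = 3)] <- "male"  # 11 male, 20 female
  ind <- individual_table(ids, sex, serum_ua = 0.30 + 0.03 * (0:30))
  rhuc_cohort(ind, do.call(rbind, geno), variants)
}

make_replication_cohort <- function() {
  variants <- local({
    cat22 <- slc22a12_pathogenic_catalog()
    cat22[cat22$protein_change %in% c("p.Trp258*", "p.Arg90His"), , drop = FALSE]
  })
  rownames(variants) <- NULL
  A <- lookup_by_protein(variants, "p.Trp258*")
  B <- lookup_by_protein(variants, "p.Arg90His")
  ids <- sprintf("R%02d", 1:50)
  cfg <- rbind(
    matrix(rep(c(2L, 0L), 10), ncol = 2, byrow = TRUE),  # hom Trp258*
    matrix(rep(c(1L, 1L), 22), ncol = 2, byrow = TRUE),  # compound het
    matrix(rep(c(0L, 2L), 1), ncol = 2, byrow = TRUE),   # hom Arg90His
    matrix(rep(c(1L, 0L), 10), ncol = 2, byrow = TRUE),  # het Trp258* only
    matrix(rep(c(0L, 1L), 4), ncol = 2, byrow = TRUE),   # het Arg90His only
    matrix(rep(c(0L, 0L), 3), ncol = 2, byrow = TRUE)    # panel negative
  )
  geno <- data.frame(
    individual_id = rep(ids, times = 2),
    variant_key = rep(c(A, B), each = 50),
    alt_count = as.integer(c(cfg[, 1], cfg[, 2])),
    hemizygous = FALSE, stringsAsFactors = FALSE
  )
  geno <- geno[geno$alt_count > 0L, , drop = FALSE]
  sex <- rep(c("male", "female"), 25)
  ind <- individual_table(ids, sex, serum_ua = 0.25 + 0.02 * (0:49))
  rhuc_cohort(ind, geno, variants)
}

# rbind variant tables with differing af_* columns by unioning them.
fill_af_cols <- function(v, cols = c("af_gnomad", "af_exac", "af_1kg")) {
  for (nm in union(cols, freq_source_cols(v)))
    if (is.null(v[[nm]])) v[[nm]] <- NA_real_
  front <- setdiff(names(v), c(grep("^af_", names(v), value = TRUE), "variant_key"))
  v[c(front, sort(grep("^af_", names(v), value = TRUE)), "variant_key")]
}
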