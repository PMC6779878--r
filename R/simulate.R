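# Synthetic screening-cohort generator.
#
# The generator emulates the genotype--phenotype structure the analysis
# assumes: bi-allelic SLC22A12 genotypes at two founder alleles plus rarer
# pathogenic alleles drive extreme hypouricemia; SLC2A9 accounts for a
# minority of genetic cases; a small fraction of non-carriers are
# hypouricemic for non-genetic (transient) reasons. Genotypes are drawn as
# two independent haplotypes per individual, each carrying at most one
# pathogenic allele, which yields Hardy-Weinberg genotype proportions at
# every site and places compound-heterozygous pairs in trans by
# construction (a configurable rate plants cis double-het pairs to exercise
# the unphased-data failure mode).

#' Simulation configuration
#'
#' Defaults describe a Korean-style adult screening population: founder
#' allele frequencies of 1.0% (p.Trp258*) and 0.3% (p.Arg90His), 0.1%
#' summed frequency of rarer pathogenic *SLC22A12* alleles, serum urate
#' 0.77 +/- 0.25 mg/dL for bi-allelic carriers (the published case mean),
#' mildly lowered urate for single heterozygotes, and a 0.03% transient
#' hypouricemia rate among non-carriers.
#'
#' @param n_individuals Cohort size (0 allowed).
#' @param seed Integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @param panel_freqs Named numeric, allele frequencies
#'   `c(trp258_stop=, arg90_his=)`.
#' @param other_pathogenic_freq Summed allele frequency of the rarer
#'   pathogenic *SLC22A12* alleles (split equally over four catalogue
#'   alleles).
#' @param other_gene_fraction Fraction of bi-allelic (genetic) cases driven
#'   by *SLC2A9* rather than *SLC22A12*.
#' @param benign_variant_rate Mean number of common benign decoy variant
#'   calls per individual.
#' @param ua_params List of `c(mean=, sd=)` per class
#'   (`biallelic_carrier`, `single_het`, `noncarrier`), mg/dL; means must
#'   be ordered `biallelic_carrier < single_het <= noncarrier`.
#' @param transient_rate P(hypouricemic urate | non-carrier): transient /
#'   malnutrition mimics.
#' @param exclusion_flag_rate Independent probability of each secondary-
#'   cause flag.
#' @param cis_pair_rate P(a non-carrier instead receives both founder
#'   alleles on one haplotype): plants cis double-hets that unphased
#'   analysis cannot distinguish from compound heterozygotes.
#' @param x_decoys Emit an X-linked benign decoy gene (hemizygous male
#'   calls).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_individuals,
                              seed = 1L,
                              panel_freqs = c(trp258_stop = 0.010,
                                              arg90_his = 0.003),
                              other_pathogenic_freq = 0.001,
                              other_gene_fraction = 0.05,
                              benign_variant_rate = 3,
                              ua_params = list(
                                biallelic_carrier = c(mean = 0.77, sd = 0.25),
                                single_het = c(mean = 4.0, sd = 1.0),
                                noncarrier = c(mean = 5.2, sd = 1.0)),
                              transient_rate = 3e-4,
                              exclusion_flag_rate = 0.08,
                              cis_pair_rate = 0,
                              x_decoys = TRUE) {
  cfg <- list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
              panel_freqs = panel_freqs,
              other_pathogenic_freq = other_pathogenic_freq,
              other_gene_fraction = other_gene_fraction,
              benign_variant_rate = benign_variant_rate,
              ua_params = ua_params, transient_rate = transient_rate,
              exclusion_flag_rate = exclusion_flag_rate,
              cis_pair_rate = cis_pair_rate, x_decoys = isTRUE(x_decoys))
  probs <- c(cfg$panel_freqs, cfg$other_pathogenic_freq,
             cfg$other_gene_fraction, cfg$transient_rate,
             cfg$exclusion_flag_rate, cfg$cis_pair_rate)
  if (any(probs < 0 | probs > 1))
    stopf("all probabilities must lie in [0,1]")
  if (sum(cfg$panel_freqs) + cfg$other_pathogenic_freq > 1)
    stopf("summed pathogenic allele frequency exceeds 1")
  if (cfg$n_individuals < 0) stopf("n_individuals must be >= 0")
  m <- vapply(cfg$ua_params, function(p) p[["mean"]], numeric(1))
  if (!(m[["biallelic_carrier"]] < m[["single_het"]] &&
        m[["single_het"]] <= m[["noncarrier"]]))
    stopf("ua means must be ordered: biallelic_carrier < single_het <= noncarrier")
  structure(cfg, class = "simulation_config")
}

rtruncnorm0 <- function(n, mean, sd) {
  # normal truncated at 0 by redraw; hypouricemia means are > 3 sd from 0
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Draw one haplotype per individual over a pathogenic allele set:
# integer 0 = none, k = allele k. P(allele k) = q[k].
draw_haplotype <- function(n, q) {
  if (n == 0L) return(integer(0))
  sample.int(length(q) + 1L, n, replace = TRUE, prob = c(1 - sum(q), q)) - 1L
}

benign_decoy_catalog <- function(rate, x_decoys) {
  qs <- numeric(0)
  if (rate > 0) {
    # per-variant carrier probability 1-(1-q)^2; pool sized to hit the rate
    m <- max(1L, as.integer(round(rate / 0.3)))
    qs <- seq(0.05, 0.30, length.out = max(m, 2L))[seq_len(m)]
  }
  n_aut <- length(qs)
  if (x_decoys) qs <- c(qs, 0.10, 0.22)
  if (!length(qs)) return(NULL)
  n <- length(qs)
  chroms <- c(rep("1", n_aut), rep("X", n - n_aut))
  genes <- c(sprintf("DECOY%d", seq_len(n_aut)),
             rep("XDECOY1", n - n_aut))
  variant_table(
    chrom = chroms, pos = 1000000L + 500L * seq_len(n),
    ref = "C", alt = "G", gene = genes,
    consequence = rep(c("missense", "synonymous"), length.out = n),
    freqs = data.frame(af_gnomad = qs, af_1kg = pmin(1, qs * 1.1)),
    known_pathogenic = FALSE
  )
}

#' Simulate a screening cohort with a genotype truth table
#'
#' @param config A [simulation_config()].
#' @return List with elements `cohort` (an `rhuc_cohort`) and `truth`
#'   (data.frame `id class causal_gene allele1 allele2`; classes
#'   `biallelic_carrier`, `single_het`, `cis_double_het`, `transient`,
#'   `noncarrier`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("S%05d", seq_len(n))
  sex <- c("male", "female")[stats::rbinom(n, 1, 0.5) + 1L]

  cat22 <- slc22a12_pathogenic_catalog()
  cat29 <- slc2a9_pathogenic_catalog()
  other_prot <- c("p.Thr217Met", "p.Leu418Arg", "p.Glu429Lys", "p.Asn136Lys")
  alle22 <- c("p.Trp258*", "p.Arg90His", other_prot)
  q22 <- c(config$panel_freqs[["trp258_stop"]], config$panel_freqs[["arg90_his"]],
           rep(config$other_pathogenic_freq / 4, 4))
  # SLC2A9 summed frequency chosen so its bi-allelic share is
  # other_gene_fraction of genetic cases
  f <- config$other_gene_fraction
  q29tot <- if (f > 0 && f < 1) sum(q22) * sqrt(f / (1 - f)) else
    if (f >= 1) stopf("other_gene_fraction must be < 1") else 0
  q29 <- rep(q29tot / 2, 2)

  hap <- cbind(draw_haplotype(n, q22), draw_haplotype(n, q22))
  hap29 <- cbind(draw_haplotype(n, q29), draw_haplotype(n, q29))

  n_alle22 <- rowSums(hap > 0L)
  n_alle29 <- rowSums(hap29 > 0L)
  class <- rep("noncarrier", n)
  causal <- rep("", n)
  class[n_alle22 + n_alle29 >= 1L] <- "single_het"
  class[n_alle29 == 2L] <- "biallelic_carrier"; causal[n_alle29 == 2L] <- "SLC2A9"
  class[n_alle22 == 2L] <- "biallelic_carrier"; causal[n_alle22 == 2L] <- "SLC22A12"

  # plant cis double-hets among noncarriers: both founder alleles on hap 1
  if (config$cis_pair_rate > 0 && n > 0) {
    nc <- which(class == "noncarrier")
    cis <- nc[stats::runif(length(nc)) < config$cis_pair_rate]
    class[cis] <- "cis_double_het"; causal[cis] <- ""
  } else cis <- integer(0)

  # transient hypouricemia among remaining noncarriers
  nc <- which(class == "noncarrier")
  tr <- nc[stats::runif(length(nc)) < config$transient_rate]
  class[tr] <- "transient"

  ua_class <- c(biallelic_carrier = "biallelic_carrier",
                single_het = "single_het",
                cis_double_het = "single_het",   # functionally one allele hit
                transient = "biallelic_carrier", # mimics the case range
                noncarrier = "noncarrier")[class]
  ua <- numeric(n)
  for (cl in unique(ua_class)) {
    i <- which(ua_class == cl)
    p <- config$ua_params[[cl]]
    ua[i] <- rtruncnorm0(length(i), p[["mean"]], p[["sd"]])
  }

  flags <- vapply(seq_len(n), function(i) {
    f <- exclusion_flag_levels()[stats::runif(6) < config$exclusion_flag_rate]
    paste(f, collapse = ",")
  }, character(1))

  # assemble genotype calls
  geno <- list()
  emit_gene <- function(hapm, alleles, keys) {
    for (k in seq_along(alleles)) {
      cnt <- (hapm[, 1] == k) + (hapm[, 2] == k)
      hit <- which(cnt > 0L)
      if (length(hit))
        geno[[length(geno) + 1L]] <<- data.frame(
          individual_id = ids[hit], variant_key = keys[k],
          alt_count = as.integer(cnt[hit]), hemizygous = FALSE,
          stringsAsFactors = FALSE)
    }
  }
  emit_gene(hap, alle22, lookup_by_protein(cat22, alle22))
  emit_gene(hap29, c(1, 2), cat29$variant_key)
  if (length(cis)) {
    fk <- lookup_by_protein(cat22, c("p.Trp258*", "p.Arg90His"))
    geno[[length(geno) + 1L]] <- data.frame(
      individual_id = rep(ids[cis], each = 2), variant_key = rep(fk, length(cis)),
      alt_count = 1L, hemizygous = FALSE, stringsAsFactors = FALSE)
  }

  decoys <- benign_decoy_catalog(config$benign_variant_rate, config$x_decoys)
  if (!is.null(decoys) && n > 0) {
    for (k in seq_len(nrow(decoys))) {
      q <- decoys$af_gnomad[k]
      if (decoys$chrom[k] %in% x_chrom_labels_default()) {
        male <- sex == "male"
        cnt <- integer(n)
        cnt[male] <- stats::rbinom(sum(male), 1, q)
        cnt[!male] <- stats::rbinom(sum(!male), 2, q)
        hemi <- male
      } else {
        cnt <- stats::rbinom(n, 2, q)
        hemi <- rep(FALSE, n)
      }
      hit <- which(cnt > 0L)
      if (length(hit))
        geno[[length(geno) + 1L]] <- data.frame(
          individual_id = ids[hit], variant_key = decoys$variant_key[k],
          alt_count = cnt[hit], hemizygous = hemi[hit],
          stringsAsFactors = FALSE)
    }
  }
  # rare non-qualifying decoys (synonymous / in-house hom / common) at
  # their catalogue frequencies
  filt <- decoy_filter_catalog()
  if (n > 0) {
    for (k in seq_len(nrow(filt))) {
      cnt <- stats::rbinom(n, 2, max(filt$af_gnomad[k], 0.002))
      hit <- which(cnt > 0L)
      if (length(hit))
        geno[[length(geno) + 1L]] <- data.frame(
          individual_id = ids[hit], variant_key = filt$variant_key[k],
          alt_count = cnt[hit], hemizygous = FALSE, stringsAsFactors = FALSE)
    }
  }

  variants <- rbind(fill_af_cols(cat22), fill_af_cols(cat29),
                    fill_af_cols(filt))
  if (!is.null(decoys)) variants <- rbind(variants, fill_af_cols(decoys))
  gtab <- if (length(geno)) do.call(rbind, geno) else genotype_table()
  ind <- individual_table(ids, sex, ua, flags)
  cohort <- rhuc_cohort(ind, gtab, variants)

  allele_name <- function(hapm, alleles) {
    a1 <- ifelse(hapm[, 1] > 0L, alleles[hapm[, 1]], "")
    a2 <- ifelse(hapm[, 2] > 0L, alleles[hapm[, 2]], "")
    cbind(a1, a2)
  }
  al <- allele_name(hap, alle22)
  al29 <- allele_name(hap29, cat29$protein_change)
  use29 <- causal == "SLC2A9"
  al[use29, ] <- al29[use29, ]
  sh29 <- class == "single_het" & n_alle29 == 1L & n_alle22 == 0L
  al[sh29, ] <- al29[sh29, ]
  if (length(cis)) { al[cis, 1] <- "p.Trp258*"; al[cis, 2] <- "p.Arg90His" }
  a1 <- ifelse(al[, 1] == "" & al[, 2] != "", al[, 2], al[, 1])
  a2 <- ifelse(al[, 1] == "" & al[, 2] != "", "", al[, 2])
  causal[class == "single_het"] <-
    ifelse(sh29[class == "single_het"], "SLC2A9", "SLC22A12")
  truth <- data.frame(id = ids, class = class, causal_gene = causal,
                      allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  truth <- truth[order(truth$id), , drop = FALSE]
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}

#' Write / read a truth table
#' @param truth Truth data.frame from [simulate_cohort()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, colClasses = "character", na.strings = NULL)
}
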