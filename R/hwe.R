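# Hardy-Weinberg goodness of fit for simulated genotype counts.

#' Chi-square goodness-of-fit test against Hardy-Weinberg proportions
#'
#' Estimates the allele frequency from the genotype counts and compares the
#' observed counts with the expected `(1-p)^2 : 2p(1-p) : p^2` proportions
#' (1 degree of freedom: three cells, one constraint, one estimated
#' parameter). Monomorphic samples return a p-value of 1.
#'
#' @param n0,n1,n2 Counts of reference-homozygous, heterozygous and
#'   alternate-homozygous genotypes.
#' @return List: `chisq`, `p_value`, `allele_freq` (estimated alternate
#'   allele frequency).
#' @export
hwe_gof <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) stopf("no genotypes")
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chisq = 0, p_value = 1, allele_freq = p))
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- c(n0, n1, n2)
  chisq <- sum((obs - expd)^2 / expd)
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       allele_freq = p)
}

#' Genotype counts at one variant over a cohort
#'
#' @param cohort An `rhuc_cohort`.
#' @param key A `variant_key`.
#' @return Integer vector `c(n0, n1, n2)` over all individuals.
#' @export
genotype_counts <- function(cohort, key) {
  g <- cohort$genotypes[cohort$genotypes$variant_key == key, , drop = FALSE]
  n <- nrow(cohort$individuals)
  c(n0 = n - nrow(g), n1 = sum(g$alt_count == 1L), n2 = sum(g$alt_count == 2L))
}
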