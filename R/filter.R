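# Four-step recessive-model filtering cascade:
#   1. population allele frequency (exclude MAF > threshold in any source)
#   2. in-house homozygote/hemizygote exclusion
#   3. consequence class (keep protein-altering / indel / splice-site)
#   4. bi-allelic requirement per gene (hom / compound het / male X hemi);
#      single heterozygotes never yield a diagnosis.
# Steps 1-3 act on variants, step 4 on each individual's genotypes.

#' Filtering-cascade configuration
#'
#' @param maf_threshold Variants with population allele frequency above
#'   this in any populated source are excluded (default 0.01, the
#'   conventional rare-variant bound). Sources with no entry contribute no
#'   evidence: a variant absent from every database survives this step.
#' @param consequence_keep Consequence classes retained by step 3.
#' @param maf_policy `"any_source_exceeds"` or `"max_across_sources"`.
#'   With per-source scalar frequencies the two give identical results
#'   (some source exceeds the bound iff the max does); both are kept for
#'   interface clarity.
#' @param x_chrom_labels Chromosome labels treated as X.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          consequence_keep = c("missense", "stop_gained",
                                               "frameshift", "inframe_indel",
                                               "splice_site"),
                          maf_policy = c("any_source_exceeds",
                                         "max_across_sources"),
                          x_chrom_labels = x_chrom_labels_default()) {
  maf_policy <- match.arg(maf_policy)
  if (!is.numeric(maf_threshold) || maf_threshold <= 0 || maf_threshold >= 1)
    stopf("maf_threshold must lie in (0,1)")
  bad <- setdiff(consequence_keep, consequence_levels())
  if (length(bad)) stopf("unknown consequence class: %s", paste(bad, collapse = ", "))
  structure(list(maf_threshold = maf_threshold,
                 consequence_keep = consequence_keep, maf_policy = maf_policy,
                 x_chrom_labels = x_chrom_labels),
            class = "filter_config")
}

#' Cascade step 1: population allele-frequency filter
#'
#' @param variants Variant table.
#' @param config A [filter_config()].
#' @return Surviving variants.
#' @export
filter_by_maf <- function(variants, config = filter_config()) {
  afc <- freq_source_cols(variants)
  if (!length(afc) || !nrow(variants)) return(variants)
  af <- as.matrix(variants[afc])
  exceeds <- switch(config$maf_policy,
    any_source_exceeds = rowSums(af > config$maf_threshold, na.rm = TRUE) > 0,
    max_across_sources = {
      mx <- suppressWarnings(apply(af, 1, max, na.rm = TRUE))
      is.finite(mx) & mx > config$maf_threshold
    })
  out <- variants[!exceeds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cascade step 2: in-house control exclusion
#'
#' Removes exactly the variants observed homozygous or hemizygous in the
#' in-house control panel; heterozygous presence in controls does not
#' remove a variant.
#'
#' @inheritParams filter_by_maf
#' @return Surviving variants.
#' @export
filter_inhouse <- function(variants) {
  out <- variants[!variants$inhouse_hom, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cascade step 3: consequence-class filter
#'
#' @inheritParams filter_by_maf
#' @return Surviving variants.
#' @export
filter_consequence <- function(variants, config = filter_config()) {
  out <- variants[variants$consequence %in% config$consequence_keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# rank qualifying genes: majority previously-reported first, then
# lexicographic; the reported `gene` field is the top-ranked one.
rank_genes <- function(genes, variants, keys_by_gene) {
  kp_share <- vapply(genes, function(g) {
    k <- keys_by_gene[[g]]
    mean(variants$known_pathogenic[match(k, variants$variant_key)])
  }, numeric(1))
  genes[order(-(kp_share > 0.5), genes)]
}

#' Cascade step 4: per-individual bi-allelic collection
#'
#' Groups the individual's genotypes over surviving variants by gene and
#' assigns the zygosity class: `homozygous` if any gene carries a
#' homozygous qualifying genotype (hom dominates extra hets in the same
#' gene), else `compound_het` if any gene carries two or more distinct
#' heterozygous qualifying alleles (phase unresolved from unphased data),
#' else `hemizygous` for a male with a qualifying allele on an X-labelled
#' chromosome, else `none`. When several genes qualify, all are retained
#' in `genes`/`qualifying`; the single `gene` field is the top-ranked one
#' (majority previously-reported, then lexicographic).
#'
#' @param individual One-row individuals data.frame (id and sex are used).
#' @param genotypes Genotype table (may cover the whole cohort; it is
#'   subset to the individual).
#' @param variants Surviving variant table (post steps 1-3).
#' @param config A [filter_config()].
#' @return One-row data.frame: `individual_id`, `gene`, `zygosity_class`,
#'   `genes` (comma-joined qualifying genes), `n_qualifying_alleles`,
#'   `phase_resolved`, and `qualifying` (list-column of the qualifying
#'   calls).
#' @export
collect_biallelic <- function(individual, genotypes, variants,
                              config = filter_config()) {
  id <- individual$individual_id[1]
  g <- genotypes[genotypes$individual_id == id, , drop = FALSE]
  diagnose_one(id, individual$sex[1], g, variants, config)
}

# core of step 4; `g` already restricted to one individual
diagnose_one <- function(id, sex, g, variants, config) {
  g <- g[g$variant_key %in% variants$variant_key, , drop = FALSE]
  vi <- match(g$variant_key, variants$variant_key)
  g$gene <- variants$gene[vi]
  g$chrom <- variants$chrom[vi]

  class_by_gene <- character(0)
  keys_by_gene <- list()
  for (gene in unique(g$gene)) {
    gg <- g[g$gene == gene, , drop = FALSE]
    on_x <- all(gg$chrom %in% config$x_chrom_labels)
    cls <- if (any(gg$alt_count == 2L)) "homozygous"
    else if (sum(gg$alt_count == 1L) >= 2L) "compound_het"
    else if (sex == "male" && on_x && nrow(gg) >= 1L) "hemizygous"
    else "none"
    if (cls != "none") {
      class_by_gene[gene] <- cls
      keys_by_gene[[gene]] <- gg$variant_key
    }
  }

  if (!length(class_by_gene)) {
    return(data.frame(individual_id = id, gene = NA_character_,
                      zygosity_class = "none", genes = "",
                      n_qualifying_alleles = 0L, phase_resolved = NA,
                      qualifying = I(list(g[0, c("variant_key", "alt_count",
                                                 "gene")])),
                      stringsAsFactors = FALSE))
  }
  cls_order <- c("homozygous", "compound_het", "hemizygous")
  top_cls <- cls_order[min(match(class_by_gene, cls_order))]
  cand <- names(class_by_gene)[class_by_gene == top_cls]
  ranked <- rank_genes(cand, variants, keys_by_gene)
  qual <- g[g$gene %in% names(class_by_gene), c("variant_key", "alt_count",
                                                "gene"), drop = FALSE]
  rownames(qual) <- NULL
  data.frame(individual_id = id, gene = ranked[1], zygosity_class = top_cls,
             genes = paste(sort(names(class_by_gene)), collapse = ","),
             n_qualifying_alleles = sum(qual$alt_count),
             phase_resolved = top_cls != "compound_het",
             qualifying = I(list(qual)), stringsAsFactors = FALSE)
}

#' Run the full filtering cascade over a set of cases
#'
#' Applies the three variant-level filters in the fixed published order
#' (frequency, in-house, consequence), then collects bi-allelic diagnoses
#' per individual. The steps commute, but the order is fixed so that
#' survival logs are comparable across runs.
#'
#' @param cohort An `rhuc_cohort` (or list with `individuals`, `genotypes`,
#'   `variants`).
#' @param cases Optional subset: character ids or an individuals
#'   data.frame; defaults to every individual in the cohort.
#' @param config A [filter_config()].
#' @return List: `diagnoses` (one row per case, see [collect_biallelic()]),
#'   `step_counts` (named integer vector: variants entering, after each
#'   variant-level step, and the count of variants used by at least one
#'   diagnosis), `surviving_variants`.
#' @export
run_cascade <- function(cohort, cases = NULL, config = filter_config()) {
  ind <- cohort$individuals
  if (is.null(cases)) cases <- ind
  if (is.character(cases)) {
    miss <- setdiff(cases, ind$individual_id)
    if (length(miss)) stopf("unknown case id: %s", paste(miss, collapse = ", "))
    cases <- ind[match(cases, ind$individual_id), , drop = FALSE]
  }
  v0 <- cohort$variants
  v1 <- filter_by_maf(v0, config)
  v2 <- filter_inhouse(v1)
  v3 <- filter_consequence(v2, config)

  g3 <- cohort$genotypes[cohort$genotypes$variant_key %in% v3$variant_key, ,
                         drop = FALSE]
  gsplit <- split(g3, factor(g3$individual_id, levels = cases$individual_id))
  empty_g <- g3[0, , drop = FALSE]
  diag <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    id <- cases$individual_id[i]
    diagnose_one(id, cases$sex[i], gsplit[[id]] %||% empty_g, v3, config)
  }))
  if (is.null(diag))
    diag <- data.frame(individual_id = character(0), gene = character(0),
                       zygosity_class = character(0), genes = character(0),
                       n_qualifying_alleles = integer(0),
                       phase_resolved = logical(0),
                       qualifying = I(list()), stringsAsFactors = FALSE)
  diag <- diag[order(diag$individual_id), , drop = FALSE]
  rownames(diag) <- NULL

  used <- unique(unlist(lapply(diag$qualifying, function(q) q$variant_key)))
  list(diagnoses = diag,
       step_counts = c(input = nrow(v0), maf = nrow(v1), inhouse = nrow(v2),
                       consequence = nrow(v3), biallelic = length(used)),
       surviving_variants = v3)
}
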