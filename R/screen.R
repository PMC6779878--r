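# Two-variant founder-panel classification (single-base-extension
# genotyping emulated as direct genotype lookup) and the cohort-level
# distribution / yield statistics.

#' Founder screening-panel definition
#'
#' Default: the two *SLC22A12* founder alleles
#' p.Trp258* (c.774G>A, rs121907892) and p.Arg90His (c.269G>A,
#' rs121907896), in that order (panel variant A and B).
#'
#' @param panel Data.frame with columns
#'   `gene cdna protein rsid chrom pos ref alt`; exactly two rows in the
#'   same gene.
#' @return A validated `panel_definition` data.frame.
#' @export
panel_definition <- function(panel = founder_panel_rows()) {
  need <- c("gene", "cdna", "protein", "rsid", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stopf("panel lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(panel) != 2L)
    stopf("the category scheme is defined for a two-variant panel")
  if (length(unique(panel$gene)) != 1L)
    stopf("panel variants must lie in one gene")
  panel$variant_key <- variant_key(panel$chrom, panel$pos, panel$ref, panel$alt)
  if (anyDuplicated(panel$variant_key)) stopf("panel variants must be distinct")
  structure(panel, class = c("panel_definition", "data.frame"))
}

#' @rdname panel_definition
#' @param path TSV path with the panel columns.
#' @export
read_panel <- function(path) {
  panel_definition(utils::read.delim(path, colClasses = c(
    gene = "character", cdna = "character", protein = "character",
    rsid = "character", chrom = "character", pos = "integer",
    ref = "character", alt = "character"), na.strings = NULL))
}

#' @rdname panel_definition
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel)[c("gene", "cdna", "protein", "rsid",
                                            "chrom", "pos", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

panel_category_levels <- function() {
  c("homA", "homB", "compound_AB", "hetA_plus_other", "hetB_plus_other",
    "hetA_only", "hetB_only", "others_only", "none")
}

#' Panel category from allele counts
#'
#' Pure function of the two panel-allele counts and the count of other
#' qualifying alleles in the panel gene. Priority: `homA`, `homB`,
#' `compound_AB`, `hetA_plus_other`, `hetB_plus_other`, `hetA_only`,
#' `hetB_only`, `others_only` (needs two or more other alleles), `none`.
#'
#' @param a,b Allele counts of panel variants A and B (0/1/2).
#' @param o Count of other qualifying alleles in the panel gene.
#' @return Character vector of categories.
#' @export
panel_category <- function(a, b, o) {
  ifelse(a == 2L, "homA",
  ifelse(b == 2L, "homB",
  ifelse(a == 1L & b == 1L, "compound_AB",
  ifelse(a == 1L & o >= 1L, "hetA_plus_other",
  ifelse(b == 1L & o >= 1L, "hetB_plus_other",
  ifelse(a == 1L, "hetA_only",
  ifelse(b == 1L, "hetB_only",
  ifelse(o >= 2L, "others_only", "none"))))))))
}

#' Classify every individual against the founder panel
#'
#' In `"wes"` mode, other qualifying alleles in the panel gene are counted
#' over the supplied post-cascade surviving variants. In `"genotyping"`
#' mode only the two panel sites are read (emulating a two-site assay, as
#' in a replication cohort typed by single-base extension): other-allele
#' counts are reported as 0 with `others_known = FALSE`, so the
#' `others_only` category cannot occur.
#'
#' @param cohort An `rhuc_cohort`.
#' @param panel A [panel_definition()].
#' @param qualifying_variants Variant table of cascade survivors (required
#'   in `"wes"` mode).
#' @param mode `"wes"` or `"genotyping"`.
#' @return Data.frame: `individual_id`, `alleles_A`, `alleles_B`,
#'   `other_alleles`, `others_known`, `category`.
#' @export
classify_panel <- function(cohort, panel = panel_definition(),
                           qualifying_variants = NULL,
                           mode = c("wes", "genotyping")) {
  mode <- match.arg(mode)
  panel <- panel_definition(as.data.frame(panel))
  miss <- setdiff(panel$variant_key, cohort$variants$variant_key)
  if (length(miss))
    stopf("panel variant absent from the cohort variant collection: %s",
          paste(panel$protein[match(miss, panel$variant_key)], collapse = ", "))
  ind <- cohort$individuals
  g <- cohort$genotypes
  count_at <- function(key) {
    cnt <- integer(nrow(ind))
    gk <- g[g$variant_key == key, , drop = FALSE]
    cnt[match(gk$individual_id, ind$individual_id)] <- gk$alt_count
    cnt
  }
  a <- count_at(panel$variant_key[1])
  b <- count_at(panel$variant_key[2])
  if (mode == "wes") {
    if (is.null(qualifying_variants))
      stopf("wes mode needs the post-cascade qualifying_variants")
    other_keys <- setdiff(
      qualifying_variants$variant_key[qualifying_variants$gene ==
                                        panel$gene[1]],
      panel$variant_key)
    go <- g[g$variant_key %in% other_keys, , drop = FALSE]
    o <- integer(nrow(ind))
    if (nrow(go)) {
      agg <- tapply(go$alt_count, go$individual_id, sum)
      o[match(names(agg), ind$individual_id)] <- as.integer(agg)
    }
    others_known <- TRUE
  } else {
    o <- integer(nrow(ind))
    others_known <- FALSE
  }
  out <- data.frame(individual_id = ind$individual_id, alleles_A = a,
                    alleles_B = b, other_alleles = o,
                    others_known = others_known,
                    category = panel_category(a, b, o),
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate the panel-category distribution of a cohort
#'
#' Produces per-category counts with percent strings rounded to one
#' decimal place, plus the two-row roll-up: any qualifying panel-gene
#' configuration versus none.
#'
#' @param classifications Output of [classify_panel()].
#' @return A `cohort_summary` list: `n`, `counts`, `percents`, `table`
#'   (category, count, pct, allele columns), `rollup`.
#' @export
tabulate_distribution <- function(classifications) {
  if (!nrow(classifications)) stopf("empty classification list")
  n <- nrow(classifications)
  lev <- panel_category_levels()
  counts <- table(factor(classifications$category, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  pct <- stats::setNames(percent_string(counts, n), lev)
  allele_cols <- c(homA = "2,0,0", homB = "0,2,0", compound_AB = "1,1,0",
                   hetA_plus_other = "1,0,1", hetB_plus_other = "0,1,1",
                   hetA_only = "1,0,0", hetB_only = "0,1,0",
                   others_only = "0,0,2+", none = "-")
  tab <- data.frame(category = lev, count = counts, pct = pct,
                    alleles = allele_cols[lev], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  any_panel_gene <- sum(counts[setdiff(lev, "none")])
  rollup <- data.frame(
    group = c("panel_gene_any", "other_than_panel_gene"),
    count = c(any_panel_gene, counts[["none"]]),
    pct = percent_string(c(any_panel_gene, counts[["none"]]), n),
    stringsAsFactors = FALSE)
  structure(list(n = n, counts = counts, percents = pct, table = tab,
                 rollup = rollup),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Panel-category distribution, n = %d\n", x$n))
  shown <- x$table[x$table$count > 0, , drop = FALSE]
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  %-16s %3d (%s)  alleles %s\n", shown$category[i],
                shown$count[i], shown$pct[i], shown$alleles[i]))
  cat(sprintf("  any panel-gene configuration: %d (%s); none: %d (%s)\n",
              x$rollup$count[1], x$rollup$pct[1],
              x$rollup$count[2], x$rollup$pct[2]))
  invisible(x)
}

#' Two-variant screening yield
#'
#' Fraction of individuals carrying at least one allele of either panel
#' variant. Deliberately permissive: single heterozygotes count as
#' screen-positive even though the trait is recessive — this is the
#' screening metric, not a diagnosis; compare [biallelic_yield()]. The
#' single-het contribution is reported explicitly.
#'
#' @param classifications Output of [classify_panel()] (one cohort or
#'   several concatenated with `rbind`).
#' @return List: `numerator`, `denominator`, `proportion`, `fraction`
#'   (e.g. `"47/50"`), `percent` (1 decimal), `n_single_het` (individuals
#'   counted positive on a single heterozygous panel allele only).
#' @export
screening_yield <- function(classifications) {
  if (!nrow(classifications)) stopf("empty classification list")
  pos <- classifications$alleles_A + classifications$alleles_B >= 1L
  single <- classifications$alleles_A + classifications$alleles_B == 1L &
    classifications$category %in% c("hetA_only", "hetB_only",
                                    "hetA_plus_other", "hetB_plus_other")
  num <- sum(pos); den <- nrow(classifications)
  list(numerator = num, denominator = den, proportion = num / den,
       fraction = sprintf("%d/%d", num, den),
       percent = percent_string(num, den), n_single_het = sum(single))
}

#' Bi-allelic diagnostic yield for a gene
#'
#' Fraction of cases whose filtering-cascade diagnosis is a bi-allelic (or
#' male hemizygous) genotype involving the given gene.
#'
#' @param diagnoses `diagnoses` data.frame from [run_cascade()].
#' @param gene Gene symbol.
#' @return List as in [screening_yield()] (without `n_single_het`).
#' @export
biallelic_yield <- function(diagnoses, gene) {
  if (!nrow(diagnoses)) stopf("empty diagnosis collection")
  hit <- diagnoses$zygosity_class != "none" &
    vapply(strsplit(diagnoses$genes, ",", fixed = TRUE),
           function(gs) gene %in% gs, logical(1))
  num <- sum(hit); den <- nrow(diagnoses)
  list(numerator = num, denominator = den, proportion = num / den,
       fraction = sprintf("%d/%d", num, den),
       percent = percent_string(num, den))
}

#' Compare computed percent strings against published ones
#'
#' Recomputes each percentage from its count and denominator and flags
#' published strings that do not match the computed rounding (for example
#' a published "6.6%" where 3/50 rounds to "6.0%"). The computed value is
#' always reported; the published string is never silently reproduced.
#'
#' @param counts Named integer vector.
#' @param denominator Cohort size.
#' @param published Named character vector of published percent strings
#'   (names matching `counts`).
#' @return Data.frame with `count`, `computed`, `published`, `mismatch`.
#' @export
compare_percent_strings <- function(counts, denominator, published) {
  nm <- names(published)
  computed <- percent_string(counts[nm], denominator)
  data.frame(name = nm, count = as.integer(counts[nm]), computed = computed,
             published = as.character(published),
             mismatch = computed != as.character(published),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Published worked-example distribution
#'
#' The two-cohort *SLC22A12* panel distribution published for the Korean
#' hypouricemia screening study, bundled as the package's worked example
#' (counts and the percent strings exactly as printed; the replication
#' "other" cell is printed as 6.6% although 3/50 rounds to 6.0% — see
#' [compare_percent_strings()]).
#'
#' @return Named list with `discovery` and `replication` data.frames
#'   (`category`, `count`, `published_pct`).
#' @export
published_distribution <- function() {
  list(
    discovery = data.frame(
      category = c("homA", "compound_AB", "homB", "hetA_plus_other",
                   "others_only", "none"),
      count = c(10L, 7L, 2L, 5L, 3L, 4L),
      published_pct = c("32.3%", "22.6%", "6.5%", "16.1%", "9.7%", "12.9%"),
      stringsAsFactors = FALSE),
    replication = data.frame(
      category = c("homA", "compound_AB", "homB", "hetA_only", "hetB_only",
                   "none"),
      count = c(10L, 22L, 1L, 10L, 4L, 3L),
      published_pct = c("20.0%", "44.0%", "2.0%", "20.0%", "8.0%", "6.6%"),
      stringsAsFactors = FALSE)
  )
}
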