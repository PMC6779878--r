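# Cohort container: annotated variants, genotypes and phenotypes, with a
# VCF 4.2 + TSV external representation.
#
# Identity of a variant throughout the package is the key chrom:pos:ref:alt
# (one ALT per record; multi-allelic sites are split on read). Protein and
# cDNA labels are opaque strings and are never parsed for positions.

#' Build an annotated variant table
#'
#' One row per alternate allele at a genomic site. Population allele
#' frequencies live in `af_<source>` columns; `NA` means the source has no
#' entry for the variant, which is treated as absence of evidence, not as
#' frequency zero.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param ref,alt Reference and single alternate allele strings.
#' @param gene Gene symbols.
#' @param consequence One of [consequence_levels()].
#' @param protein_change,cdna_change Optional HGVS-p / HGVS-c labels (`NA`
#'   when absent); opaque strings keyed to transcript NM_144585.2 for
#'   *SLC22A12* entries.
#' @param freqs Optional data.frame (or named list) of per-source allele
#'   frequencies in `[0, 1]`; column names must start with `af_`.
#' @param inhouse_hom Logical: seen homozygous/hemizygous in the in-house
#'   control panel.
#' @param known_pathogenic Logical: previously reported disease-causing
#'   (HGMD-style membership flag, supplied as input).
#' @return A data.frame with a `variant_key` column (`chrom:pos:ref:alt`).
#' @export
variant_table <- function(chrom, pos, ref, alt, gene, consequence,
                          protein_change = NA_character_,
                          cdna_change = NA_character_,
                          freqs = NULL,
                          inhouse_hom = FALSE,
                          known_pathogenic = FALSE) {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(gene), length(consequence))
  v <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    gene = as.character(gene),
    consequence = as.character(consequence),
    protein_change = rep_len(as.character(protein_change), n),
    cdna_change = rep_len(as.character(cdna_change), n),
    inhouse_hom = rep_len(as.logical(inhouse_hom), n),
    known_pathogenic = rep_len(as.logical(known_pathogenic), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(freqs)) {
    freqs <- as.data.frame(freqs)
    if (!all(grepl("^af_", names(freqs))))
      stopf("frequency columns must be named af_<source>")
    for (nm in names(freqs)) v[[nm]] <- as.numeric(freqs[[nm]])
  }
  v$variant_key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  validate_variants(v)
  v
}

#' Names of the allele-frequency source columns of a variant table
#' @param variants A variant table.
#' @return Character vector of `af_*` column names (possibly empty).
#' @export
freq_source_cols <- function(variants) {
  grep("^af_", names(variants), value = TRUE)
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "inhouse_hom", "known_pathogenic", "variant_key")
  miss <- setdiff(need, names(v))
  if (length(miss)) stopf("variant table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(v$pos < 1L)) stopf("variant positions must be >= 1")
  if (any(v$ref == v$alt)) stopf("ref and alt must differ")
  if (any(grepl(",", v$alt, fixed = TRUE)))
    stopf("one alternate allele per record; split multi-allelic sites upstream")
  bad <- setdiff(unique(v$consequence), consequence_levels())
  if (length(bad)) stopf("unknown consequence class: %s", paste(bad, collapse = ", "))
  for (nm in freq_source_cols(v)) {
    f <- v[[nm]]
    if (any(!is.na(f) & (f < 0 | f > 1)))
      stopf("allele frequencies in %s must lie in [0,1]", nm)
  }
  if (anyDuplicated(v$variant_key))
    stopf("duplicate variant_key: %s", v$variant_key[duplicated(v$variant_key)][1])
  invisible(v)
}

#' Build a phenotype (individuals) table
#'
#' @param individual_id Unique subject identifiers.
#' @param sex "male" or "female"; unknown sex is a hard error because
#'   hemizygosity calls depend on it.
#' @param serum_ua Serum uric acid in mg/dL, non-negative.
#' @param flags Comma-separated subsets of [exclusion_flag_levels()]
#'   (`""` for none).
#' @return A data.frame with one row per subject.
#' @export
individual_table <- function(individual_id, sex, serum_ua, flags = "") {
  d <- data.frame(
    individual_id = as.character(individual_id),
    sex = as.character(sex),
    serum_ua = as.numeric(serum_ua),
    flags = rep_len(as.character(flags), length(individual_id)),
    stringsAsFactors = FALSE
  )
  validate_individuals(d)
  d
}

validate_individuals <- function(d) {
  if (anyDuplicated(d$individual_id)) stopf("duplicate individual_id")
  bad <- setdiff(unique(d$sex), c("male", "female"))
  if (length(bad))
    stopf("sex must be 'male' or 'female' for every individual (got: %s)",
          paste(bad, collapse = ", "))
  if (any(is.na(d$serum_ua) | d$serum_ua < 0))
    stopf("serum_ua must be present and non-negative")
  allf <- unique(unlist(lapply(d$flags, split_flags)))
  badf <- setdiff(allf, exclusion_flag_levels())
  if (length(badf)) stopf("unknown exclusion flag: %s", paste(badf, collapse = ", "))
  invisible(d)
}

#' Build a genotype table (carrier calls only)
#'
#' Long format: one row per (individual, variant) with a nonzero alternate
#' allele count. `alt_count` 0 calls are never stored.
#'
#' @param individual_id Subject id per call.
#' @param variant_key `chrom:pos:ref:alt` key per call.
#' @param alt_count 1 or 2 (1 only, when hemizygous).
#' @param hemizygous Logical; male X-chromosome call.
#' @return data.frame of calls.
#' @export
genotype_table <- function(individual_id = character(0),
                           variant_key = character(0),
                           alt_count = integer(0),
                           hemizygous = FALSE) {
  g <- data.frame(
    individual_id = as.character(individual_id),
    variant_key = as.character(variant_key),
    alt_count = as.integer(alt_count),
    hemizygous = rep_len(as.logical(hemizygous), length(individual_id)),
    stringsAsFactors = FALSE
  )
  validate_genotypes(g)
  g
}

validate_genotypes <- function(g) {
  if (any(!g$alt_count %in% c(1L, 2L)))
    stopf("alt_count must be 1 or 2 (zero-count calls are dropped)")
  if (any(g$hemizygous & g$alt_count != 1L))
    stopf("hemizygous calls must have alt_count 1")
  if (anyDuplicated(g[c("individual_id", "variant_key")]))
    stopf("an individual's genotypes must reference distinct variants")
  invisible(g)
}

#' Assemble a cohort object
#'
#' Ties together a phenotype table, a genotype table and a variant table and
#' enforces referential integrity plus hemizygosity consistency (a call is
#' hemizygous exactly when the subject is male and the variant sits on a
#' chromosome labelled X).
#'
#' @param individuals From [individual_table()].
#' @param genotypes From [genotype_table()].
#' @param variants From [variant_table()].
#' @return An object of class `rhuc_cohort` (list with the three tables,
#'   canonically ordered: variants by chrom/pos/ref/alt, individuals by id).
#' @export
rhuc_cohort <- function(individuals, genotypes, variants) {
  validate_individuals(individuals)
  validate_genotypes(genotypes)
  validate_variants(variants)
  dangle <- setdiff(genotypes$variant_key, variants$variant_key)
  if (length(dangle))
    stopf("genotype references unknown variant_key: %s", paste(dangle, collapse = ", "))
  orphan <- setdiff(genotypes$individual_id, individuals$individual_id)
  if (length(orphan))
    stopf("genotype references unknown individual: %s", paste(orphan, collapse = ", "))
  # hemizygosity must agree with (sex, chromosome)
  if (nrow(genotypes)) {
    sex <- individuals$sex[match(genotypes$individual_id, individuals$individual_id)]
    chrom <- variants$chrom[match(genotypes$variant_key, variants$variant_key)]
    expect_hemi <- sex == "male" & chrom %in% x_chrom_labels_default()
    if (any(genotypes$hemizygous != expect_hemi))
      stopf("hemizygous flag inconsistent with sex/chromosome for %d call(s)",
            sum(genotypes$hemizygous != expect_hemi))
  }
  x <- structure(list(individuals = individuals, genotypes = genotypes,
                      variants = variants),
                 class = "rhuc_cohort")
  sort_cohort(x)
}

# Canonical ordering used by writers and equality tests.
sort_cohort <- function(x) {
  v <- x$variants[order(x$variants$chrom, x$variants$pos, x$variants$ref,
                        x$variants$alt), , drop = FALSE]
  i <- x$individuals[order(x$individuals$individual_id), , drop = FALSE]
  g <- x$genotypes[order(match(x$genotypes$individual_id, i$individual_id),
                         match(x$genotypes$variant_key, v$variant_key)), ,
                   drop = FALSE]
  rownames(v) <- rownames(i) <- rownames(g) <- NULL
  structure(list(individuals = i, genotypes = g, variants = v),
            class = "rhuc_cohort")
}

#' @export
print.rhuc_cohort <- function(x, ...) {
  cat(sprintf("rhuc_cohort: %d individuals, %d variants, %d carrier calls\n",
              nrow(x$individuals), nrow(x$variants), nrow(x$genotypes)))
  cat(sprintf("  genes: %s\n",
              paste(sort(unique(x$variants$gene)), collapse = ", ")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Phenotype TSV

#' Read / write the phenotype table
#'
#' Tab-separated with header `id sex ua flags`; `flags` is a comma-separated
#' subset of [exclusion_flag_levels()] or empty.
#'
#' @param path File path.
#' @return `read_phenotype` returns an individuals data.frame.
#' @export
read_phenotype <- function(path) {
  d <- utils::read.delim(path, colClasses = c("character", "character",
                                              "numeric", "character"),
                         na.strings = NULL)
  names(d) <- c("individual_id", "sex", "serum_ua", "flags")
  validate_individuals(d)
  d
}

#' @rdname read_phenotype
#' @param individuals Individuals data.frame.
#' @export
write_phenotype <- function(individuals, path) {
  validate_individuals(individuals)
  out <- data.frame(id = individuals$individual_id, sex = individuals$sex,
                    ua = sprintf("%.17g", individuals$serum_ua),
                    flags = individuals$flags)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## VCF writer (package dialect: VCF 4.2, GT-only FORMAT, per-alt INFO)

vcf_info_headers <- function(sources) {
  c('##INFO=<ID=GENE,Number=A,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=A,Type=String,Description="Consequence class">',
    '##INFO=<ID=PCH,Number=A,Type=String,Description="Protein change (HGVS-p)">',
    '##INFO=<ID=CDC,Number=A,Type=String,Description="cDNA change (HGVS-c)">',
    sprintf('##INFO=<ID=AF_%s,Number=A,Type=Float,Description="Allele frequency, %s">',
            sources, sources),
    '##INFO=<ID=IHH,Number=A,Type=Integer,Description="Homozygous/hemizygous in in-house controls (0/1)">',
    '##INFO=<ID=KP,Number=A,Type=Integer,Description="Previously reported pathogenic (0/1)">')
}

info_str <- function(x) ifelse(is.na(x), ".", as.character(x))
info_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))

#' Write a cohort as VCF + phenotype TSV
#'
#' Emits a multi-sample VCF 4.2 with one ALT per record, GT-only FORMAT and
#' the package's INFO dialect (`GENE`, `CSQ`, `PCH`, `CDC`, `AF_<source>`,
#' `IHH`, `KP`, all `Number=A`). Record order is deterministic
#' (chrom, pos, ref, alt); male genotypes on X-labelled chromosomes are
#' written haploid.
#'
#' @param cohort An `rhuc_cohort`.
#' @param vcf_path,phenotype_path Output paths.
#' @return Invisibly, `vcf_path`.
#' @export
write_cohort <- function(cohort, vcf_path, phenotype_path) {
  cohort <- rhuc_cohort(cohort$individuals, cohort$genotypes, cohort$variants)
  v <- cohort$variants
  ind <- cohort$individuals
  g <- cohort$genotypes
  write_phenotype(ind, phenotype_path)

  sources <- sub("^af_", "", freq_source_cols(v))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=rhucscreen-%s",
                   as.character(utils::packageVersion("rhucscreen"))),
           sprintf("##contig=<ID=%s>", unique(v$chrom)),
           vcf_info_headers(sources),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  nsam <- nrow(ind)
  if (nsam > 0) cols <- c(cols, "FORMAT", ind$individual_id)
  lines <- c(hdr, paste(cols, collapse = "\t"))

  if (nrow(v)) {
    info <- paste0("GENE=", v$gene, ";CSQ=", v$consequence,
                   ";PCH=", info_str(v$protein_change),
                   ";CDC=", info_str(v$cdna_change))
    for (s in sources)
      info <- paste0(info, ";AF_", s, "=", info_num(v[[paste0("af_", s)]]))
    info <- paste0(info, ";IHH=", as.integer(v$inhouse_hom),
                   ";KP=", as.integer(v$known_pathogenic))

    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", info, sep = "\t")
    if (nsam > 0) {
      # allele-count matrix: variants x samples
      ac <- matrix(0L, nrow(v), nsam,
                   dimnames = list(v$variant_key, ind$individual_id))
      if (nrow(g)) ac[cbind(g$variant_key, g$individual_id)] <- g$alt_count
      haploid <- outer(v$chrom %in% x_chrom_labels_default(), ind$sex == "male", `&`)
      gt <- matrix(c("0/0", "0/1", "1/1")[ac + 1L], nrow(v), nsam)
      gt[haploid] <- c("0", "1")[pmin(ac[haploid], 1L) + 1L]
      body <- paste(body, "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, vcf_path)
  invisible(vcf_path)
}

## ---------------------------------------------------------------------------
## VCF reader (delegates parsing to VariantAnnotation, then maps the dialect)

#' Annotation field mapping for VCF input
#'
#' Names the INFO subfields that carry the annotation the pipeline needs.
#' Defaults match the package's own writer dialect.
#'
#' @param gene,consequence,protein,cdna,inhouse,known INFO field IDs.
#' @param freq_prefix Prefix shared by all allele-frequency INFO fields; the
#'   suffix becomes the source name.
#' @return Named list used by [read_cohort()].
#' @export
annotation_spec <- function(gene = "GENE", consequence = "CSQ", protein = "PCH",
                            cdna = "CDC", inhouse = "IHH", known = "KP",
                            freq_prefix = "AF_") {
  list(gene = gene, consequence = consequence, protein = protein, cdna = cdna,
       inhouse = inhouse, known = known, freq_prefix = freq_prefix)
}

# Per-alt value from an INFO column that may be atomic or a List.
info_alt_value <- function(col, i, j, default = NA) {
  if (is.null(col)) return(default)
  x <- if (is.list(col) || methods::is(col, "List")) col[[i]] else col[i]
  if (length(x) >= j) x[[j]] else if (length(x) == 1L) x[[1L]] else default
}

#' Read a cohort from VCF + phenotype TSV
#'
#' Multi-allelic records are split into one entry per alternate allele
#' (`Number=A` INFO fields are distributed accordingly). Genotypes are
#' converted to per-alt allele counts; zero counts are dropped. An
#' unrecognisable consequence string degrades to `"other"` with a warning;
#' a sample-set mismatch between the VCF and the phenotype table is a hard
#' error listing the symmetric difference.
#'
#' @param vcf_path,phenotype_path Input paths.
#' @param spec An [annotation_spec()].
#' @return An `rhuc_cohort`.
#' @export
read_cohort <- function(vcf_path, phenotype_path, spec = annotation_spec()) {
  ind <- read_phenotype(phenotype_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  samples <- colnames(vcf)

  only_vcf <- setdiff(samples, ind$individual_id)
  only_phe <- setdiff(ind$individual_id, samples)
  if (length(only_vcf) || length(only_phe))
    stopf("sample sets differ: VCF-only {%s}; phenotype-only {%s}",
          paste(only_vcf, collapse = ","), paste(only_phe, collapse = ","))

  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  if (!methods::is(alts, "List")) alts <- S4Vectors::List(as.list(as.character(alts)))
  info <- VariantAnnotation::info(vcf)
  gtm <- if ("GT" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$GT else NULL

  afcols <- grep(paste0("^", spec$freq_prefix), names(info), value = TRUE)
  sources <- tolower(sub(paste0("^", spec$freq_prefix), "", afcols))

  vlist <- list(); glist <- list()
  nsite <- length(rr)
  for (i in seq_len(nsite)) {
    site_alts <- as.character(alts[[i]])
    gts <- if (is.null(gtm)) character(0) else gtm[i, , drop = TRUE]
    toks <- strsplit(gts, "[/|]")
    hemi_cell <- !grepl("[/|]", gts) & gts != "."
    for (j in seq_along(site_alts)) {
      csq <- as.character(info_alt_value(info[[spec$consequence]], i, j,
                                         NA_character_))
      if (is.na(csq) || !csq %in% consequence_levels()) {
        warnf("unparseable consequence %s at %s:%d; using 'other'",
              if (is.na(csq)) "<missing>" else shQuote(csq), chrom[i], pos[i])
        csq <- "other"
      }
      row <- data.frame(
        chrom = chrom[i], pos = as.integer(pos[i]), ref = refs[i],
        alt = site_alts[j],
        gene = as.character(info_alt_value(info[[spec$gene]], i, j, NA_character_)),
        consequence = csq,
        protein_change = as.character(info_alt_value(info[[spec$protein]], i, j,
                                                     NA_character_)),
        cdna_change = as.character(info_alt_value(info[[spec$cdna]], i, j,
                                                  NA_character_)),
        inhouse_hom = isTRUE(as.integer(info_alt_value(info[[spec$inhouse]], i, j,
                                                       0L)) == 1L),
        known_pathogenic = isTRUE(as.integer(info_alt_value(info[[spec$known]], i,
                                                            j, 0L)) == 1L),
        stringsAsFactors = FALSE
      )
      for (k in seq_along(afcols)) {
        val <- suppressWarnings(as.numeric(info_alt_value(info[[afcols[k]]], i, j,
                                                          NA_real_)))
        row[[paste0("af_", sources[k])]] <- val
      }
      vlist[[length(vlist) + 1L]] <- row

      if (length(gts)) {
        cnt <- vapply(toks, function(t) sum(t == as.character(j)), integer(1))
        hit <- which(cnt > 0L)
        if (length(hit))
          glist[[length(glist) + 1L]] <- data.frame(
            individual_id = samples[hit],
            variant_key = variant_key(chrom[i], pos[i], refs[i], site_alts[j]),
            alt_count = cnt[hit],
            hemizygous = hemi_cell[hit],
            stringsAsFactors = FALSE
          )
      }
    }
  }
  v <- if (length(vlist)) do.call(rbind, vlist) else
    variant_table(character(0), integer(0), character(0), character(0),
                  character(0), character(0))
  # sentinel "." decodes to NA for the optional opaque labels
  v$protein_change[v$protein_change %in% "."] <- NA_character_
  v$cdna_change[v$cdna_change %in% "."] <- NA_character_
  v$variant_key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  g <- if (length(glist)) do.call(rbind, glist) else genotype_table()
  rhuc_cohort(ind, g, v)
}
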