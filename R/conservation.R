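# Ortholog conservation profiling and external-predictor aggregation for
# candidate missense variants, plus the joined per-individual / per-variant
# report. External predictors (PolyPhen-2, SIFT, Condel, Mutation Taster)
# are never executed: their printed verdicts are inputs.

aa_three_to_one <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

#' Normalize an amino-acid residue symbol
#'
#' Accepts one-letter or three-letter codes in any case and returns the
#' canonical one-letter code. The Asp/Asn (and Glu/Gln) distinction is
#' preserved exactly; an unknown symbol is a hard error.
#'
#' @param x Character vector of residue symbols.
#' @return One-letter codes.
#' @export
normalize_residue <- function(x) {
  x <- trimws(as.character(x))
  out <- character(length(x))
  one <- toupper(x) %in% aa_three_to_one
  out[one] <- toupper(x[one])
  three <- !one
  if (any(three)) {
    key <- paste0(toupper(substring(x[three], 1, 1)),
                  tolower(substring(x[three], 2)))
    hit <- aa_three_to_one[key]
    if (anyNA(hit))
      stopf("not an amino-acid symbol: %s",
            paste(unique(x[three][is.na(hit)]), collapse = ", "))
    out[three] <- unname(hit)
  }
  out
}

#' Ortholog conservation profile of one residue
#'
#' A species is scored conserved when its aligned residue is identical to
#' the human reference residue.
#'
#' @param human_residue Human reference residue (1- or 3-letter).
#' @param ortholog_residues Residues aligned to the ortholog species, in
#'   species order (names retained if present).
#' @return List: `n_conserved`, `n_species`, `fraction`, `matches`
#'   (logical, species order).
#' @export
conservation_profile <- function(human_residue, ortholog_residues) {
  if (!length(ortholog_residues)) stopf("ortholog residue list is empty")
  h <- normalize_residue(human_residue)
  o <- normalize_residue(ortholog_residues)
  m <- o == h
  names(m) <- names(ortholog_residues)
  list(n_conserved = sum(m), n_species = length(m),
       fraction = mean(m), matches = m)
}

# verdict token -> {deleterious, benign} dictionary; tokens may carry a
# parenthesised score ("Dam(0.998)") which is stripped before lookup.
verdict_dictionary <- function() {
  list(
    deleterious = c("dc", "disease_causing", "dam", "damaging", "del",
                    "deleterious", "d", "probably_damaging",
                    "possibly_damaging"),
    benign = c("bn", "benign", "tol", "tolerated", "neu", "neutral", "pm",
               "polymorphism", "b", "n")
  )
}

map_verdict_token <- function(token) {
  t <- tolower(trimws(sub("\\(.*\\)$", "", token)))
  d <- verdict_dictionary()
  out <- ifelse(t %in% d$deleterious, "deleterious",
                ifelse(t %in% d$benign, "benign", "ambiguous"))
  unknown <- out == "ambiguous" & nzchar(t)
  if (any(unknown))
    warnf("unknown verdict token(s) mapped to ambiguous: %s",
          paste(unique(token[unknown]), collapse = ", "))
  out
}

#' Aggregate external-predictor verdicts for one variant
#'
#' Each tool's vocabulary is mapped onto deleterious / benign / ambiguous
#' through a fixed dictionary (DC, Dam, Del, damaging... are deleterious;
#' Bn, Tol, Neu, PM... are benign; unknown tokens become ambiguous with a
#' warning). Consensus is the majority over non-ambiguous calls; a tie —
#' or no usable call — is ambiguous.
#'
#' @param verdicts Named character vector, tool -> verdict token (scores in
#'   parentheses are ignored).
#' @return List: `consensus`, `tally` (named counts), `per_tool` (mapped
#'   labels).
#' @export
aggregate_verdicts <- function(verdicts) {
  if (!length(verdicts)) stopf("at least one tool verdict is required")
  mapped <- map_verdict_token(verdicts)
  names(mapped) <- names(verdicts)
  tally <- c(deleterious = sum(mapped == "deleterious"),
             benign = sum(mapped == "benign"),
             ambiguous = sum(mapped == "ambiguous"))
  consensus <- if (tally[["deleterious"]] > tally[["benign"]]) "deleterious"
  else if (tally[["benign"]] > tally[["deleterious"]]) "benign"
  else "ambiguous"
  list(consensus = consensus, tally = tally, per_tool = mapped)
}

#' Bundled evidence for the four novel URAT1 missense variants
#'
#' Ortholog residues (rhesus macaque, mouse, dog, African elephant) and the
#' four external-predictor verdicts for the novel *SLC22A12* missense
#' variants of the Korean hypouricemia study, shipped as a plain-text
#' worked example under `inst/extdata/`.
#'
#' @return Data.frame, one row per variant.
#' @export
urat1_novel_missense <- function() {
  path <- system.file("extdata", "urat1_novel_missense.tsv",
                      package = "rhucscreen", mustWork = TRUE)
  utils::read.delim(path, na.strings = c("NA", ""), colClasses = "character")
}

#' Conservation profiles for an evidence table
#'
#' @param evidence Data.frame with `protein_change`, `human_residue` and
#'   one column per ortholog species (as in [urat1_novel_missense()]).
#' @param species Column names of the ortholog residues, in panel order.
#' @return Data.frame: `protein_change`, `n_conserved`, `n_species`,
#'   `fraction`, plus one logical match column per species.
#' @export
conservation_table <- function(evidence,
                               species = c("rhesus_macaque", "mus_musculus",
                                           "canis_lupus_familiaris",
                                           "loxodonta_africana")) {
  miss <- setdiff(c("protein_change", "human_residue", species),
                  names(evidence))
  if (length(miss)) stopf("evidence lacks columns: %s", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    prof <- conservation_profile(evidence$human_residue[i],
                                 stats::setNames(unlist(evidence[i, species]),
                                                 species))
    cbind(data.frame(protein_change = evidence$protein_change[i],
                     n_conserved = prof$n_conserved,
                     n_species = prof$n_species, fraction = prof$fraction,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(prof$matches)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Verdict aggregation for an evidence table
#'
#' @param evidence Data.frame with `protein_change` and one column per
#'   tool.
#' @param tools Tool column names.
#' @return Data.frame: `protein_change`, `n_deleterious`, `n_benign`,
#'   `n_ambiguous`, `consensus`.
#' @export
verdict_table <- function(evidence,
                          tools = c("mutation_taster", "pp2_humvar", "sift",
                                    "condel")) {
  miss <- setdiff(c("protein_change", tools), names(evidence))
  if (length(miss)) stopf("evidence lacks columns: %s", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    agg <- aggregate_verdicts(stats::setNames(unlist(evidence[i, tools]), tools))
    data.frame(protein_change = evidence$protein_change[i],
               n_deleterious = agg$tally[["deleterious"]],
               n_benign = agg$tally[["benign"]],
               n_ambiguous = agg$tally[["ambiguous"]],
               consensus = agg$consensus, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the joined diagnostic report
#'
#' Joins cascade diagnoses with panel classifications per individual and
#' assembles a per-variant evidence table over all alleles used in at
#' least one diagnosis, annotating novelty (no prior pathogenicity
#' report), conservation and predictor consensus where supplied. Compound-
#' heterozygous rows carry an explicit unresolved-phase caveat.
#'
#' @param diagnoses `diagnoses` from [run_cascade()].
#' @param classifications Output of [classify_panel()] for the same
#'   individuals.
#' @param variants Variant table covering the qualifying alleles.
#' @param conservation Optional [conservation_table()] output keyed by
#'   `protein_change`.
#' @param verdicts Optional [verdict_table()] output keyed by
#'   `protein_change`.
#' @return An `rhuc_report` list: `per_individual`, `per_variant`,
#'   `markdown` (character vector of report lines).
#' @export
build_report <- function(diagnoses, classifications, variants,
                         conservation = NULL, verdicts = NULL) {
  if (!setequal(diagnoses$individual_id, classifications$individual_id))
    stopf("diagnoses and classifications cover different individuals")
  cl <- classifications[match(diagnoses$individual_id,
                              classifications$individual_id), , drop = FALSE]
  per_ind <- data.frame(
    individual_id = diagnoses$individual_id,
    gene = diagnoses$gene, zygosity_class = diagnoses$zygosity_class,
    qualifying_alleles = vapply(diagnoses$qualifying, function(q)
      paste(sprintf("%s x%d", q$variant_key, q$alt_count), collapse = ";"),
      character(1)),
    panel_category = cl$category,
    phase_caveat = ifelse(diagnoses$zygosity_class == "compound_het",
                          "phase unresolved (cis/trans unknown)", ""),
    stringsAsFactors = FALSE)

  used <- unique(unlist(lapply(diagnoses$qualifying, function(q) q$variant_key)))
  dangling <- setdiff(used, variants$variant_key)
  if (length(dangling))
    stopf("qualifying alleles missing from the variant table: %s",
          paste(dangling, collapse = ", "))
  pv <- variants[variants$variant_key %in% used, , drop = FALSE]
  per_var <- data.frame(
    variant_key = pv$variant_key, gene = pv$gene,
    protein_change = pv$protein_change, consequence = pv$consequence,
    novel = !pv$known_pathogenic,
    n_carriers = vapply(pv$variant_key, function(k)
      sum(vapply(diagnoses$qualifying, function(q) k %in% q$variant_key,
                 logical(1))), integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(conservation)) {
    i <- match(per_var$protein_change, conservation$protein_change)
    per_var$conserved <- ifelse(is.na(i), NA_character_,
                                sprintf("%d/%d", conservation$n_conserved[i],
                                        conservation$n_species[i]))
  }
  if (!is.null(verdicts)) {
    i <- match(per_var$protein_change, verdicts$protein_change)
    per_var$prediction_consensus <- ifelse(is.na(i), NA_character_,
                                           verdicts$consensus[i])
    per_var$prediction_tally <- ifelse(is.na(i), NA_character_,
                                       sprintf("%d:%d", verdicts$n_deleterious[i],
                                               verdicts$n_benign[i]))
  }
  per_var <- per_var[order(per_var$gene, per_var$variant_key), , drop = FALSE]
  rownames(per_var) <- NULL

  md <- c("# Diagnostic report", "",
          sprintf("Individuals: %d; qualifying variants: %d; novel: %d",
                  nrow(per_ind), nrow(per_var), sum(per_var$novel)), "",
          "## Per individual", df_to_md(per_ind), "",
          "## Per variant", df_to_md(per_var))
  structure(list(per_individual = per_ind, per_variant = per_var,
                 markdown = md), class = "rhuc_report")
}

#' @export
print.rhuc_report <- function(x, ...) {
  cat(x$markdown, sep = "\n")
  invisible(x)
}

df_to_md <- function(d) {
  if (!nrow(d)) return(paste0("| ", paste(names(d), collapse = " | "), " |"))
  fmt <- function(v) ifelse(is.na(v), "", as.character(v))
  c(paste0("| ", paste(names(d), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|"),
    vapply(seq_len(nrow(d)), function(i)
      paste0("| ", paste(vapply(d[i, ], fmt, character(1)), collapse = " | "),
             " |"), character(1)))
}
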