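# Candidate-gene screen: sequence-ontology impact classes, membrane
# annotation, and consistency of per-line genotypes with line-level
# serological knowledge.

#' Classify a coding effect into a sequence-ontology impact class
#'
#' A rule-based stand-in for annotation-tool impact assignment:
#' `stop_gained`/`frameshift` are HIGH, `missense` MODERATE,
#' `splice_region`/`synonymous` LOW, `intronic`/`intergenic` MODIFIER.
#'
#' @param coding_effect Character vector of effect terms.
#' @return Character vector of impact classes.
#' @export
classify_impact <- function(coding_effect) {
  map <- c(missense = "MODERATE", stop_gained = "HIGH", frameshift = "HIGH",
           splice_region = "LOW", synonymous = "LOW",
           intronic = "MODIFIER", intergenic = "MODIFIER")
  bad <- setdiff(unique(coding_effect), names(map))
  if (length(bad)) {
    stop("annotation error: unknown coding effect term(s): ",
         paste(bad, collapse = ", "))
  }
  unname(map[coding_effect])
}

#' Retain variants with HIGH or MODERATE impact
#'
#' @param variants Data frame with an `impact` column.
#' @return The subset with `impact` in `{HIGH, MODERATE}`.
#' @export
select_impactful <- function(variants) {
  variants[variants$impact %in% c("HIGH", "MODERATE"), , drop = FALSE]
}

#' Default membrane cellular-component term set
#' @export
membrane_terms_default <- function() {
  c("plasma membrane", "integral component of membrane", "cell surface")
}

#' Filter genes to those annotated on cell-surface membranes
#'
#' Keeps genes whose cellular-component terms intersect the membrane term
#' set (case-insensitive).
#'
#' @param genes Data frame with `gene_id` and `cellular_components`
#'   (semicolon-separated terms).
#' @param terms Membrane term set; see [membrane_terms_default()].
#' @return The membrane-annotated subset of `genes`.
#' @export
membrane_filter <- function(genes, terms = membrane_terms_default()) {
  terms <- tolower(trimws(terms))
  keep <- vapply(genes$cellular_components, function(cc) {
    if (is.na(cc) || !nzchar(cc)) return(FALSE)
    comp <- tolower(trimws(strsplit(cc, ";", fixed = TRUE)[[1]]))
    any(comp %in% terms)
  }, logical(1))
  genes[keep, , drop = FALSE]
}

# genotype columns of a variant table = line ids of the supplied profiles
.line_geno <- function(variants, line_ids) {
  miss <- setdiff(line_ids, colnames(variants))
  if (length(miss)) {
    stop("variant table lacks genotype column(s) for line(s): ",
         paste(miss, collapse = ", "))
  }
  g <- as.matrix(variants[, line_ids, drop = FALSE])
  valid <- c("hom-ref", "het", "hom-alt", "missing")
  if (!all(g %in% valid | is.na(g))) {
    stop("format error: genotype calls must be one of ",
         paste(valid, collapse = ", "))
  }
  g[is.na(g)] <- "missing"
  g
}

#' Check a gene's variants for consistency with line serology
#'
#' Over the gene's HIGH/MODERATE-impact variants, four checks are computed:
#'
#' * `same_allele_identity`: all fixed lines sharing a serological allele are
#'   homozygous with identical genotype vectors;
#' * `cross_allele_difference`: fixed lines with different alleles differ at
#'   at least one variant;
#' * `segregation_present`: every segregating line shows a heterozygous call,
#'   or both homozygous classes among its calls;
#' * `fixation_respected`: no fixed line has a heterozygous call.
#'
#' Missing calls are excluded per comparison and counted. The gene passes iff
#' all four checks hold; a gene with no impactful variants fails with reason
#' `"no-impactful-variants"`.
#'
#' @param gene_id Gene to check.
#' @param variants Variant table (columns as in [simulate_variant_table()]).
#' @param profiles Line profiles (`line_id`, `status`, list-column
#'   `alleles`).
#' @return List `gene_id`, `n_impactful`, `checks` (named logical vector),
#'   `pass`, `reason`, `n_missing_ignored`.
#' @export
consistency_check <- function(gene_id, variants, profiles) {
  known <- profiles[profiles$status %in% c("fixed", "segregating"), ,
                    drop = FALSE]
  if (nrow(known) < 2L) stop("need >= 2 line profiles with known status")
  v <- select_impactful(variants[variants$gene_id == gene_id, , drop = FALSE])
  if (nrow(v) == 0L) {
    return(list(gene_id = gene_id, n_impactful = 0L,
                checks = c(same_allele_identity = FALSE,
                           cross_allele_difference = FALSE,
                           segregation_present = FALSE,
                           fixation_respected = FALSE),
                pass = FALSE, reason = "no-impactful-variants",
                n_missing_ignored = 0L))
  }
  g <- .line_geno(v, known$line_id)   # variants x lines
  n_missing <- sum(g == "missing")
  fixed <- known[known$status == "fixed", , drop = FALSE]
  segr <- known[known$status == "segregating", , drop = FALSE]

  # (a) fixed lines sharing an allele: identical, homozygous
  chk_a <- TRUE
  if (nrow(fixed)) {
    fixed_allele <- vapply(fixed$alleles, `[[`, "", 1)
    for (al in unique(fixed_allele)) {
      cols <- fixed$line_id[fixed_allele == al]
      sub <- g[, cols, drop = FALSE]
      if (any(sub == "het")) chk_a <- FALSE
      if (length(cols) > 1L) {
        for (r in seq_len(nrow(sub))) {
          calls <- sub[r, ]
          calls <- calls[calls != "missing"]
          if (length(unique(calls)) > 1L) chk_a <- FALSE
        }
      }
    }
  }

  # (b) fixed lines with different alleles differ somewhere
  chk_b <- TRUE
  if (nrow(fixed) > 1L) {
    fixed_allele <- vapply(fixed$alleles, `[[`, "", 1)
    pairs <- utils::combn(seq_len(nrow(fixed)), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (fixed_allele[i] == fixed_allele[j]) next
      gi <- g[, fixed$line_id[i]]; gj <- g[, fixed$line_id[j]]
      usable <- gi != "missing" & gj != "missing"
      if (!any(gi[usable] != gj[usable])) chk_b <- FALSE
    }
  }

  # (c) segregating lines show segregation
  chk_c <- TRUE
  for (l in segr$line_id) {
    calls <- g[, l]
    calls <- calls[calls != "missing"]
    if (!length(calls)) { chk_c <- FALSE; next }
    if (!(any(calls == "het") ||
          (any(calls == "hom-ref") && any(calls == "hom-alt")))) chk_c <- FALSE
  }

  # (d) fixed lines never heterozygous
  chk_d <- !nrow(fixed) || !any(g[, fixed$line_id, drop = FALSE] == "het")

  checks <- c(same_allele_identity = chk_a, cross_allele_difference = chk_b,
              segregation_present = chk_c, fixation_respected = chk_d)
  list(gene_id = gene_id, n_impactful = nrow(v), checks = checks,
       pass = all(checks), reason = if (all(checks)) "" else
         paste(names(checks)[!checks], collapse = ","),
       n_missing_ignored = n_missing)
}

#' Rank candidate genes in a region
#'
#' Candidates are the genes that both carry membrane annotation and pass the
#' four consistency checks, ordered by the number of supporting impactful
#' variants (descending, ties by gene id). Every gene is reported with its
#' verdict regardless of outcome; an empty candidate set returns an empty
#' table plus the full audit, not an error.
#'
#' @param genes Gene annotation data frame (`gene_id`,
#'   `cellular_components`, ...).
#' @param variants Variant table.
#' @param profiles Line profiles.
#' @param terms Membrane term set.
#' @return List `candidates` (data frame `gene_id`, `n_impactful`) and
#'   `audit` (per-gene verdict data frame).
#' @export
rank_candidates <- function(genes, variants, profiles,
                            terms = membrane_terms_default()) {
  mem <- membrane_filter(genes, terms)$gene_id
  verdicts <- lapply(genes$gene_id, consistency_check, variants = variants,
                     profiles = profiles)
  audit <- data.frame(
    gene_id = vapply(verdicts, `[[`, "", "gene_id"),
    membrane = genes$gene_id %in% mem,
    n_impactful = vapply(verdicts, function(v) as.integer(v$n_impactful),
                         integer(1)),
    pass = vapply(verdicts, `[[`, NA, "pass"),
    reason = vapply(verdicts, `[[`, "", "reason"),
    n_missing_ignored = vapply(verdicts, function(v)
      as.integer(v$n_missing_ignored), integer(1)),
    stringsAsFactors = FALSE)
  for (nm in names(verdicts[[1]]$checks)) {
    audit[[nm]] <- vapply(verdicts, function(v) v$checks[[nm]], logical(1))
  }
  cand <- audit[audit$membrane & audit$pass, , drop = FALSE]
  cand <- cand[order(-cand$n_impactful, cand$gene_id), c("gene_id",
                                                         "n_impactful")]
  rownames(cand) <- NULL
  list(candidates = cand, audit = audit)
}
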