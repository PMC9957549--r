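# Haplotype registry operations: allele-vector encoding, protein-level
# (missense) projection, Hamming distances, and stable label assignment.

#' Encode a haplotype registry as an alt-allele indicator matrix
#'
#' @param registry Data frame with a `label` column and one allele column per
#'   panel assay (as returned by [load_panel_fixture()]).
#' @param panel Panel data frame defining assay order and ref/alt alleles.
#' @return Integer matrix (haplotypes x assays), 1 where the haplotype carries
#'   the alternate allele. Row names are haplotype labels.
#' @export
hap_alt_matrix <- function(registry, panel) {
  stopifnot(all(panel$assay_id %in% colnames(registry)))
  m <- matrix(0L, nrow(registry), nrow(panel),
              dimnames = list(registry$label, panel$assay_id))
  for (j in seq_len(nrow(panel))) {
    a <- registry[[panel$assay_id[j]]]
    bad <- !(a %in% c(panel$ref_allele[j], panel$alt_allele[j]))
    if (any(bad)) {
      stop("registry allele not in {ref, alt} for assay ", panel$assay_id[j],
           ": ", paste(unique(a[bad]), collapse = ", "))
    }
    m[, j] <- as.integer(a == panel$alt_allele[j])
  }
  m
}

#' Project a haplotype onto its missense (protein-changing) sites
#'
#' Haplotypes identical in this projection encode the same protein and are
#' expected to be serologically indistinguishable (e.g. the CD99-H06
#' haplotype projects identically to CD99-H03 and therefore to a D3 protein).
#'
#' @param hap Character vector of alleles over the panel (panel order), or a
#'   single haplotype label present in `registry`.
#' @param panel Panel data frame.
#' @param registry Optional registry to look `hap` up in when it is a label.
#' @return Named character vector of alleles at the missense assays.
#' @export
nonsyn_projection <- function(hap, panel, registry = NULL) {
  keep <- panel$coding_effect == "missense" & !is.na(panel$coding_effect)
  if (!any(keep)) stop("panel contains no missense markers")
  if (length(hap) == 1L && !is.null(registry) && hap %in% registry$label) {
    hap <- unlist(registry[registry$label == hap, panel$assay_id])
  }
  if (length(hap) != nrow(panel)) {
    stop("haplotype length ", length(hap), " does not match panel size ",
         nrow(panel))
  }
  stats::setNames(as.character(hap)[keep], panel$assay_id[keep])
}

#' Partition a registry into protein-identity classes
#'
#' Groups haplotypes by their missense projection: members of one class are
#' predicted to produce identical proteins.
#'
#' @inheritParams hap_alt_matrix
#' @return Named list of character vectors of haplotype labels; names are the
#'   concatenated missense allele patterns.
#' @export
protein_classes <- function(registry, panel) {
  proj <- vapply(registry$label, function(l) {
    paste(nonsyn_projection(l, panel, registry), collapse = "")
  }, character(1))
  split(registry$label, proj)
}

#' Hamming distance between two haplotypes over a panel
#'
#' @param h1,h2 Haplotype labels (looked up in `registry`) or allele vectors
#'   in panel order.
#' @param panel Panel data frame.
#' @param registry Registry for label lookup.
#' @param sites Which assays to compare: all, only missense, or only
#'   synonymous.
#' @return List with `count` (number of differing assays) and `markers`
#'   (their assay ids).
#' @examples
#' fx <- load_panel_fixture()
#' hamming_haplotypes("CD99-H11", "CD99-H01", fx$panel, fx$registry)
#' @export
hamming_haplotypes <- function(h1, h2, panel, registry = NULL,
                               sites = c("all", "missense", "synonymous")) {
  sites <- match.arg(sites)
  fetch <- function(h) {
    if (length(h) == 1L && !is.null(registry) && h %in% registry$label) {
      h <- unlist(registry[registry$label == h, panel$assay_id])
    }
    if (length(h) != nrow(panel)) {
      stop("haplotype length does not match panel (", nrow(panel), " assays)")
    }
    as.character(h)
  }
  a <- fetch(h1); b <- fetch(h2)
  keep <- switch(sites,
                 all = rep(TRUE, nrow(panel)),
                 missense = panel$coding_effect == "missense",
                 synonymous = panel$coding_effect == "synonymous")
  diff <- keep & (a != b)
  list(count = sum(diff), markers = panel$assay_id[diff])
}

.hap_index <- function(label) {
  as.integer(sub("^.*-H", "", label))
}

#' Register haplotype vectors under stable labels
#'
#' Vectors already present in the registry keep their labels; novel vectors
#' are appended in input order and labelled `<prefix>-H<nn>` using the next
#' free index after the current maximum. Existing labels are never renumbered,
#' so historical numbering gaps are preserved.
#'
#' @param vectors Data frame or matrix of allele columns (one row per
#'   haplotype, columns = panel assays) to register.
#' @param registry Existing registry data frame (`label` + assay columns).
#' @param prefix Label prefix, e.g. `"CD99"`.
#' @return List with `registry` (augmented) and `labels` (label assigned to
#'   each input row, in input order).
#' @export
register_labels <- function(vectors, registry, prefix = "CD99") {
  assays <- setdiff(colnames(registry), "label")
  vectors <- as.data.frame(vectors, stringsAsFactors = FALSE)
  if (!all(assays %in% colnames(vectors))) {
    stop("vectors must provide a column for every registry assay")
  }
  key <- function(df) apply(df[, assays, drop = FALSE], 1, paste, collapse = "|")
  reg_keys <- key(registry)
  if (anyDuplicated(registry$label)) stop("registry error: duplicate labels")
  next_idx <- if (nrow(registry)) max(.hap_index(registry$label)) + 1L else 1L
  labels <- character(nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    k <- key(vectors[i, , drop = FALSE])
    hit <- match(k, reg_keys)
    if (!is.na(hit)) {
      labels[i] <- registry$label[hit]
    } else {
      lab <- sprintf("%s-H%02d", prefix, next_idx)
      if (lab %in% registry$label) stop("registry error: label collision ", lab)
      next_idx <- next_idx + 1L
      row <- c(list(label = lab), as.list(vectors[i, assays]))
      registry <- rbind(registry, as.data.frame(row, stringsAsFactors = FALSE))
      reg_keys <- c(reg_keys, k)
      labels[i] <- lab
    }
  }
  list(registry = registry, labels = labels)
}
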