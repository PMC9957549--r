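# Homozygote-anchored Clark parsimony phasing over a marker panel. The panel
# spans ~11 kb, treated as fully linked (no recombination, no imputation).

.hap_key <- function(v) paste(v, collapse = "")

#' Extract haplotypes carried by fully homozygous individuals
#'
#' Every individual with a complete genotype (no missing calls) that is
#' homozygous at every assay contributes its single haplotype; duplicates
#' are merged.
#'
#' @param geno Integer matrix (individuals x assays) of alt-allele dosages
#'   in `{0, 1, 2, NA}`.
#' @param panel Panel data frame (supplies assay order/names).
#' @return Integer 0/1 matrix of distinct haplotypes (rows), columns = assay
#'   ids.
#' @export
haplotypes_from_homozygotes <- function(geno, panel) {
  stopifnot(ncol(geno) == nrow(panel))
  complete <- !apply(is.na(geno), 1, any)
  hom <- complete & apply(geno == 0L | geno == 2L, 1, all)
  haps <- unique(geno[hom, , drop = FALSE] / 2L)
  haps <- matrix(as.integer(haps), ncol = ncol(geno),
                 dimnames = list(NULL, panel$assay_id))
  haps
}

#' Clark-parsimony phasing against a known haplotype set
#'
#' Individuals are processed in order of ascending heterozygous-site count,
#' ties broken by individual id. Each is resolved if its genotype equals the
#' sum of one known haplotype and one complement that is itself known or
#' thereby new:
#'
#' * if exactly one unordered pair of known haplotypes explains the genotype,
#'   it is resolved to that pair;
#' * if two or more known pairs explain it, it is left unresolved with the
#'   candidate set (no guessing);
#' * if no known pair fits and the genotype is complete, complements of known
#'   haplotypes are tried; among explanations introducing one new haplotype,
#'   the known partner most frequent among already-resolved individuals is
#'   preferred (ties by discovery order). The new complement joins the known
#'   set.
#'
#' Genotypes with missing calls are matched against known pairs at their
#' non-missing sites only and never spawn new haplotypes. Every resolved
#' diplotype reproduces the observed genotype at every non-missing assay.
#'
#' @param geno Integer matrix (individuals x assays), entries
#'   `{0, 1, 2, NA}`; rownames are individual ids.
#' @param known Integer 0/1 matrix of known haplotypes (e.g. from
#'   [haplotypes_from_homozygotes()] or a registry via [hap_alt_matrix()]).
#' @return List: `results` data frame (`individual_id`, `hap1`, `hap2` as
#'   keys into `known`, `resolved`, `n_candidates`), `candidates` (named
#'   list of candidate pair matrices for unresolved individuals), `known`
#'   (augmented 0/1 matrix with key rownames).
#' @export
clark_phase <- function(geno, known) {
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("format error: genotypes must be dosages in {0, 1, 2, NA}")
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("ind%04d", seq_len(nrow(geno)))
  }
  known <- matrix(as.integer(known), ncol = ncol(geno),
                  dimnames = list(NULL, colnames(geno)))
  known <- unique(known)
  keys <- apply(known, 1, .hap_key)
  rownames(known) <- keys
  counts <- stats::setNames(rep(0L, length(keys)), keys)

  n_het <- rowSums(geno == 1L, na.rm = TRUE)
  ord <- order(n_het, rownames(geno))

  res <- data.frame(individual_id = rownames(geno)[ord],
                    hap1 = NA_character_, hap2 = NA_character_,
                    resolved = FALSE, n_candidates = 0L,
                    stringsAsFactors = FALSE)
  cand_out <- list()

  explain_known <- function(g) {
    ok <- !is.na(g)
    out <- list()
    for (i in seq_len(nrow(known))) {
      comp <- g - known[i, ]
      valid <- all(comp[ok] %in% c(0L, 1L)) # complement must be a haplotype
      if (!valid) next
      for (j in i:nrow(known)) {
        if (all((known[i, ] + known[j, ])[ok] == g[ok])) {
          out[[length(out) + 1L]] <- c(rownames(known)[i], rownames(known)[j])
        }
      }
    }
    unique(lapply(out, sort))
  }

  for (r in seq_len(nrow(res))) {
    id <- res$individual_id[r]
    g <- geno[id, ]
    expl <- explain_known(g)
    if (length(expl) == 1L) {
      pair <- expl[[1]]
    } else if (length(expl) >= 2L) {
      res$n_candidates[r] <- length(expl)
      cand_out[[id]] <- do.call(rbind, expl)
      next
    } else {
      if (any(is.na(g))) next   # incomplete genotypes never spawn haplotypes
      new_opts <- list()
      for (i in seq_len(nrow(known))) {
        comp <- g - known[i, ]
        if (all(comp %in% c(0L, 1L))) {
          new_opts[[length(new_opts) + 1L]] <-
            list(partner = rownames(known)[i], comp = as.integer(comp))
        }
      }
      if (!length(new_opts)) next
      # greedy Clark: prefer the most frequently seen known partner,
      # ties by discovery order in the known set
      freq <- vapply(new_opts, function(o) counts[[o$partner]], integer(1))
      disc <- vapply(new_opts, function(o) match(o$partner, rownames(known)),
                     integer(1))
      pick <- new_opts[[order(-freq, disc)[1]]]
      newk <- .hap_key(pick$comp)
      known <- rbind(known, matrix(pick$comp, 1,
                                   dimnames = list(newk, colnames(geno))))
      counts[newk] <- 0L
      pair <- sort(c(pick$partner, newk))
    }
    res$hap1[r] <- pair[1]; res$hap2[r] <- pair[2]
    res$resolved[r] <- TRUE
    counts[pair[1]] <- counts[pair[1]] + 1L
    counts[pair[2]] <- counts[pair[2]] + 1L
  }
  res <- res[order(match(res$individual_id, rownames(geno))), ]
  rownames(res) <- NULL
  list(results = res, candidates = cand_out, known = known)
}

#' Label phased diplotypes against a registry
#'
#' Convenience wrapper: converts `clark_phase()` haplotype keys to registry
#' labels, registering any novel haplotypes under the next free label.
#'
#' @param phased Output of [clark_phase()].
#' @param registry Registry data frame (`label` + assay columns).
#' @param panel Panel data frame.
#' @param prefix Label prefix for novel haplotypes.
#' @return List `results` (with `hap1`/`hap2` as labels) and `registry`
#'   (possibly augmented).
#' @export
label_phase_results <- function(phased, registry, panel, prefix = "CD99") {
  alt <- hap_alt_matrix(registry, panel)
  key2lab <- stats::setNames(rownames(alt), apply(alt, 1, .hap_key))
  used <- rownames(phased$known)
  novel <- setdiff(used, names(key2lab))
  if (length(novel)) {
    vecs <- do.call(rbind, lapply(novel, function(k) {
      bits <- as.integer(strsplit(k, "")[[1]])
      vapply(seq_len(nrow(panel)), function(j) {
        if (bits[j] == 1L) panel$alt_allele[j] else panel$ref_allele[j]
      }, character(1))
    }))
    colnames(vecs) <- panel$assay_id
    reg <- register_labels(as.data.frame(vecs, stringsAsFactors = FALSE),
                           registry, prefix)
    registry <- reg$registry
    key2lab[novel] <- reg$labels
  }
  out <- phased$results
  out$hap1 <- unname(key2lab[out$hap1])
  out$hap2 <- unname(key2lab[out$hap2])
  list(results = out, registry = registry)
}
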