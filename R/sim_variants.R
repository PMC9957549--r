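# Construction of annotated variant tables with known screening truth: the
# causal gene's missense variants track serological allele identity exactly;
# decoys are built to fail exactly one of the two screens (membrane
# annotation, line-consistency).

#' Derive line profiles from a simulation configuration
#'
#' Translates each line's haplotype inventory through the truth map to the
#' serological alleles it carries. Lines containing any unmapped haplotype
#' get status `"unknown"` and are ignored by the consistency screen,
#' mirroring breeds genotyped without serology.
#'
#' @param config A `sim_config`.
#' @param truth_map Named character vector, haplotype label -> serological
#'   allele (`NA` = unknown). Defaults to the packaged assignments.
#' @return Data frame `line_id`, `breed`, `status`, list-column `alleles`.
#' @export
line_profiles <- function(config, truth_map = load_panel_fixture()$serology) {
  rows <- lapply(seq_len(nrow(config$lines)), function(i) {
    haps <- names(config$lines$freqs[[i]])
    alle <- unname(truth_map[haps])
    status <- config$lines$status[i]
    if (any(is.na(alle))) {
      status <- "unknown"
      alle <- NA_character_
    } else {
      alle <- sort(unique(alle))
      if (status == "fixed" && length(alle) != 1L) {
        stop("configuration error: line ", config$lines$line_id[i],
             " declared fixed but carries alleles ",
             paste(alle, collapse = ", "))
      }
    }
    list(line_id = config$lines$line_id[i], breed = config$lines$breed[i],
         status = status, alleles = list(alle))
  })
  out <- data.frame(line_id = vapply(rows, `[[`, "", "line_id"),
                    breed = vapply(rows, `[[`, "", "breed"),
                    status = vapply(rows, `[[`, "", "status"),
                    stringsAsFactors = FALSE)
  out$alleles <- lapply(rows, function(r) r$alleles[[1]])
  out
}

#' Simulate an annotated variant table with screening truth
#'
#' Builds a per-line variant table for the causal region such that only the
#' causal gene survives the combined membrane + consistency screen:
#'
#' * the causal gene carries one missense (MODERATE) variant per non-reference
#'   serological allele, whose per-line genotypes correspond perfectly to
#'   allele identity (fixed lines homozygous, segregating lines heterozygous
#'   at the variants marking their alleles), plus synonymous (LOW) variants;
#' * membrane-annotated decoys carry missense variants that are monomorphic
#'   across lines (no tracking: they fail the cross-allele-difference and
#'   segregation checks);
#' * non-membrane decoys replicate the causal genotype pattern but are
#'   excluded by the membrane filter.
#'
#' @inheritParams line_profiles
#' @return List: `variants` (data frame `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `gene_id`, `effect`, `impact`, plus one genotype column per line with
#'   calls in `hom-ref`/`het`/`hom-alt`/`missing`), `genes` (annotation data
#'   frame with `cellular_components`), `profiles` (from [line_profiles()]).
#' @export
simulate_variant_table <- function(config,
                                   truth_map = load_panel_fixture()$serology) {
  profiles <- line_profiles(config, truth_map)
  known <- profiles[profiles$status %in% c("fixed", "segregating"), ]
  if (nrow(known) < 2L) {
    stop("configuration error: need >= 2 lines with known serology")
  }
  alleles <- sort(unique(unlist(known$alleles)))
  ref_allele <- alleles[1]
  marked <- setdiff(alleles, ref_allele)

  region <- config$causal_region
  gene_ids <- c(config$causal_gene, config$decoy_genes$gene_id)
  span <- 12000L; gap <- 50000L
  if (region$end - region$start + 1L < length(gene_ids) * (span + gap)) {
    stop("configuration error: causal region too small for ",
         length(gene_ids), " genes")
  }
  starts <- region$start + (seq_along(gene_ids) - 1L) * (span + gap)
  genes <- data.frame(gene_id = gene_ids, chrom = region$chrom,
                      start = starts, end = starts + span,
                      stringsAsFactors = FALSE)
  membrane <- c(TRUE, config$decoy_genes$membrane)
  genes$cellular_components <- ifelse(
    membrane, "plasma membrane;integral component of membrane", "cytoplasm")

  # genotype of a line at the variant marking allele S
  geno_for <- function(line_alleles, S) {
    n_alt <- sum(line_alleles == S)
    if (length(line_alleles) == 1L) {           # fixed
      if (line_alleles == S) "hom-alt" else "hom-ref"
    } else if (S %in% line_alleles) "het" else "hom-ref"
  }

  line_ids <- profiles$line_id
  mk_variants <- function(gene, tracking) {
    gstart <- genes$start[genes$gene_id == gene]
    vs <- lapply(seq_along(marked), function(k) {
      S <- marked[k]
      g <- vapply(seq_len(nrow(profiles)), function(i) {
        if (!profiles$status[i] %in% c("fixed", "segregating")) return("missing")
        if (tracking) geno_for(profiles$alleles[[i]], S) else "hom-ref"
      }, character(1))
      row <- data.frame(chrom = region$chrom, pos = gstart + 1000L * k,
                        id = sprintf("%s_mis%d", gene, k),
                        ref = "G", alt = "A", gene_id = gene,
                        effect = "missense",
                        impact = classify_impact("missense"),
                        stringsAsFactors = FALSE)
      row[line_ids] <- as.list(g)
      row
    })
    # synonymous companions (LOW impact, ignored by the screen)
    syn <- lapply(seq_len(2), function(k) {
      S <- marked[1 + (k - 1) %% length(marked)]
      g <- vapply(seq_len(nrow(profiles)), function(i) {
        if (!profiles$status[i] %in% c("fixed", "segregating")) return("missing")
        if (tracking) geno_for(profiles$alleles[[i]], S) else "hom-ref"
      }, character(1))
      row <- data.frame(chrom = region$chrom,
                        pos = gstart + 9000L + 100L * k,
                        id = sprintf("%s_syn%d", gene, k),
                        ref = "C", alt = "T", gene_id = gene,
                        effect = "synonymous",
                        impact = classify_impact("synonymous"),
                        stringsAsFactors = FALSE)
      row[line_ids] <- as.list(g)
      row
    })
    do.call(rbind, c(vs, syn))
  }

  tracking <- c(TRUE, config$decoy_genes$tracks_serology)
  variants <- do.call(rbind, lapply(seq_along(gene_ids), function(i) {
    mk_variants(gene_ids[i], tracking[i])
  }))
  rownames(variants) <- NULL
  list(variants = variants, genes = genes, profiles = profiles)
}
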