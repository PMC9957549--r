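# Plain-text readers/writers for the pipeline's external formats. VCF
# reading goes through vcfR; writing emits uncompressed VCF 4.2 directly
# (the table is small and the genotype encoding is line-level).

.gt_code <- c(`hom-ref` = "0/0", het = "0/1", `hom-alt` = "1/1",
              missing = "./.")

#' Write a per-line variant table as VCF
#'
#' Emits an uncompressed VCF 4.2 with `GENE`, `EFFECT` and `IMPACT` INFO
#' keys and one genotype column per line.
#'
#' @param variants Variant data frame as produced by
#'   [simulate_variant_table()].
#' @param path Output file.
#' @param line_ids Genotype columns to write; defaults to every column after
#'   the annotation block.
#' @export
write_variant_vcf <- function(variants, path,
                              line_ids = setdiff(colnames(variants),
                                                 c("chrom", "pos", "id",
                                                   "ref", "alt", "gene_id",
                                                   "effect", "impact"))) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
           "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", line_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- sprintf("GENE=%s;EFFECT=%s;IMPACT=%s", v$gene_id, v$effect,
                    v$impact)
    gts <- unname(.gt_code[unlist(v[line_ids])])
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-line variant table from VCF
#'
#' Reads a VCF with `GENE=` and `EFFECT=` (or `IMPACT=`) INFO keys and GT
#' genotype columns back into the data-frame form used by the screen.
#'
#' @param path VCF file.
#' @return Variant data frame (`chrom`, `pos`, `id`, `ref`, `alt`,
#'   `gene_id`, `effect`, `impact`, one call column per sample/line).
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info1 <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  effect <- info1("EFFECT")
  impact <- info1("IMPACT")
  if (all(is.na(impact)) && !all(is.na(effect))) {
    impact <- classify_impact(effect)
  }
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    gene_id = info1("GENE"), effect = effect,
                    impact = impact, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  back <- stats::setNames(names(.gt_code), .gt_code)
  for (s in colnames(gt)) {
    calls <- gsub("|", "/", gt[, s], fixed = TRUE)
    calls[is.na(calls)] <- "./."
    calls[calls == "1/0"] <- "0/1"
    out[[s]] <- unname(back[calls])
    out[[s]][is.na(out[[s]])] <- "missing"
  }
  out
}

#' Write the generator's outputs as plain-text files
#'
#' Writes individuals + pedigree (CSV), serology (CSV), pool manifest (CSV),
#' pool intensities (TSV matrix), variants (VCF) and genes (BED with name
#' and membrane-term column).
#'
#' @param sim List with any of `population`, `serology`, `pools`,
#'   `intensity`, `variants`, `genes`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(obj, file, fun) {
    p <- file.path(dir, file); fun(obj, p); paths[[file]] <<- p
  }
  if (!is.null(sim$population)) {
    w(sim$population, "individuals.csv",
      function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  if (!is.null(sim$serology)) {
    w(sim$serology, "serology.csv",
      function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  if (!is.null(sim$pools)) {
    w(sim$pools, "pools.csv",
      function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }
  if (!is.null(sim$intensity)) {
    w(sim$intensity, "intensity.tsv", function(o, p) {
      utils::write.table(data.frame(pool_id = rownames(o), o,
                                    check.names = FALSE),
                         p, sep = "\t", row.names = FALSE, quote = FALSE)
    })
  }
  if (!is.null(sim$variants)) {
    w(sim$variants, "variants.vcf", write_variant_vcf)
  }
  if (!is.null(sim$genes)) {
    w(sim$genes, "genes.bed", function(o, p) {
      bed <- data.frame(chrom = o$chrom, start = o$start - 1L, end = o$end,
                        name = o$gene_id,
                        components = o$cellular_components)
      utils::write.table(bed, p, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    })
  }
  invisible(paths)
}
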