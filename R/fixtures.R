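# Packaged fixtures: the 8-marker CD99 PACE panel, its 11 haplotypes, the
# known haplotype -> serological allele assignments, and a candidate-region
# gene table used by the membrane screen.

.fixture_md5 <- c(
  cd99_panel.csv      = "bb75663fb6fe4c5c353c55b6cddcf76a",
  cd99_haplotypes.csv = "78007e00da4332e8f3d5a73ed97ace34",
  cd99_serology.csv   = "8923a696094d3ec833e39554f1732e06"
)

.fixture_path <- function(file, dir = NULL) {
  if (is.null(dir)) {
    path <- system.file("extdata", file, package = "alloanchor")
    if (!nzchar(path)) stop("fixture file not found: ", file)
  } else {
    path <- file.path(dir, file)
  }
  path
}

.check_fixture <- function(path, file) {
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(.fixture_md5[file]))) {
    stop("fixture integrity error: checksum mismatch for ", file,
         " (expected ", .fixture_md5[file], ", got ", got, ")")
  }
  invisible(path)
}

#' Load the CD99 marker panel and haplotype registry fixture
#'
#' Returns the 8-assay PACE panel spanning CD99 exons 2 through 11 (7 SNPs and
#' one intronic splice-region indel, GRCg6a 1-based coordinates) together with
#' the registry of the 11 haplotypes observed across research and elite layer
#' lines, and the serological alleles known for a subset of them
#' (H01 = D1, H02 = D2, H03/H04/H06 = D3).
#'
#' Panel rows follow assay order (exon 2 first); because CD99 runs against the
#' genomic coordinate axis here, positions decrease along the panel. The
#' registry preserves the published label numbering, including haplotypes
#' (H05, H09) with no known serology. The registry row for CD99-H10 is encoded
#' as CD99-H04 plus the alternate allele at the synonymous L185L assay
#' (rs735519530): this is the only configuration consistent with all reported
#' facts, namely that the 11 haplotypes are distinct, that CD99-H06 matches the
#' reference genome at every assay, and that CD99-H10 differs from CD99-H04 by
#' a single synonymous SNP.
#'
#' Files are verified against frozen MD5 checksums; a mismatch raises an
#' integrity error.
#'
#' @param dir Directory containing the fixture CSVs. Defaults to the copies
#'   installed with the package; override only for testing.
#' @return A list with elements `panel` (data frame, one row per assay),
#'   `registry` (data frame: `label` plus one allele column per assay) and
#'   `serology` (named character vector, haplotype label -> serological
#'   allele, `NA` where unknown).
#' @examples
#' fx <- load_panel_fixture()
#' nrow(fx$registry)            # 11 haplotypes
#' sum(fx$panel$variant_class == "snp")  # 7 SNPs
#' @export
load_panel_fixture <- function(dir = NULL) {
  paths <- vapply(names(.fixture_md5), function(f) {
    p <- .fixture_path(f, dir)
    .check_fixture(p, f)
    p
  }, character(1))

  panel <- utils::read.csv(paths["cd99_panel.csv"],
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  panel$pos <- as.integer(gsub(",", "", panel$pos))
  registry <- utils::read.csv(paths["cd99_haplotypes.csv"],
                              colClasses = "character",
                              stringsAsFactors = FALSE)
  sero <- utils::read.csv(paths["cd99_serology.csv"],
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  serology <- sero$allele
  serology[!nzchar(serology)] <- NA_character_
  names(serology) <- sero$label

  stopifnot(identical(colnames(registry)[-1], panel$assay_id))
  list(panel = panel, registry = registry, serology = serology)
}

#' Candidate-region gene annotation table
#'
#' A gene table for the chromosome 1 candidate region (129.7 to 131.4 Mb)
#' used by [membrane_filter()]: the five genes annotated with membrane
#' cellular-component terms (ARSD, ARSE, CD99, P2RY8, SLC25A6) plus
#' non-membrane co-resident genes. The non-membrane entries, all coordinates
#' and the exact term strings are synthetic (illustrative), which is why the
#' underlying file is named `region_genes_synthetic.csv`; only the membership
#' of the membrane set reflects the region's published annotation.
#'
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `cellular_components` (semicolon-separated terms).
#' @examples
#' genes <- region_gene_fixture()
#' membrane_filter(genes)$gene_id
#' @export
region_gene_fixture <- function() {
  path <- .fixture_path("region_genes_synthetic.csv")
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  g$chrom <- as.character(g$chrom)
  g
}
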