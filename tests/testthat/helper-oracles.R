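# Independent oracles used across tests: these deliberately avoid the
# package's own code paths.

fx <- load_panel_fixture()

# squared Pearson correlation via the raw sum formula
pearson_r2_brute <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num^2 / den
}

# brute-force MAF/missingness filter, written independently of qc_filter
qc_brute <- function(dosages, maf_min, missing_max) {
  keep <- logical(ncol(dosages))
  for (j in seq_len(ncol(dosages))) {
    x <- dosages[, j]
    miss <- sum(is.na(x)) / length(x)
    xo <- x[!is.na(x)]
    f <- if (length(xo)) sum(xo) / (2 * length(xo)) else NA
    maf <- if (is.na(f)) 0 else min(f, 1 - f)
    keep[j] <- maf >= maf_min && miss <= missing_max
  }
  colnames(dosages)[keep]
}

# enumerate every unordered haplotype pair explaining a dosage genotype
explain_brute <- function(g, alt) {
  out <- list()
  for (i in seq_len(nrow(alt))) for (j in i:nrow(alt)) {
    if (all(alt[i, ] + alt[j, ] == g)) {
      out[[length(out) + 1L]] <- sort(rownames(alt)[c(i, j)])
    }
  }
  out
}

# unordered diplotype key
dip_key <- function(h1, h2) paste(pmin(h1, h2), pmax(h1, h2))

# a tiny line-profile table builder
mk_profiles <- function(...) {
  specs <- list(...)
  out <- data.frame(
    line_id = vapply(specs, `[[`, "", 1),
    breed = "WL",
    status = vapply(specs, `[[`, "", 2),
    stringsAsFactors = FALSE)
  out$alleles <- lapply(specs, `[[`, 3)
  out
}
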