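# Pooled-GWAS stage: genotype recoding, array QC, per-SNP regression of
# serology-expected allele counts on pool intensities (r2 scoring), a
# confirmation trend-test scan on individual genotypes, and candidate-region
# delimitation.

#' Recode genotype calls to B-allele dosages
#'
#' Maps `AA -> 0`, `AB -> 1`, `BB -> 2` (the count of B-allele copies);
#' missing calls (`NA` or empty strings) stay missing.
#'
#' @param m Character matrix or data frame of calls, samples x markers.
#' @return Integer matrix of dosages with the same dimnames.
#' @export
recode_calls <- function(m) {
  m <- as.matrix(m)
  codes <- c(AA = 0L, AB = 1L, BB = 2L)
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  known <- m %in% names(codes)
  missing <- is.na(m) | m == ""
  if (any(!known & !missing)) {
    bad <- which(!known & !missing, arr.ind = TRUE)[1, ]
    stop("format error: unknown genotype symbol \"", m[bad[1], bad[2]],
         "\" at row ", if (!is.null(rownames(m))) rownames(m)[bad[1]] else bad[1],
         ", column ", if (!is.null(colnames(m))) colnames(m)[bad[2]] else bad[2])
  }
  out[known] <- codes[m[known]]
  out
}

#' Quality-control filter on a dosage matrix
#'
#' Retains a marker iff its minor allele frequency is at least `maf_min` and
#' its missing fraction is at most `missing_max`. MAF is `min(f, 1 - f)` of
#' the B-allele frequency over non-missing calls.
#'
#' @param dosages Numeric matrix, samples x markers, entries in
#'   `{0, 1, 2, NA}`.
#' @param maf_min Minimum minor allele frequency (default 0.1).
#' @param missing_max Maximum missing-call fraction (default 0.1).
#' @return List with `keep` (retained marker names) and `audit` (data frame
#'   `marker`, `maf`, `missing_frac`, `retained`, `reason`; reason is
#'   `"maf"`, `"missing"`, `"maf+missing"` or `""`).
#' @export
qc_filter <- function(dosages, maf_min = 0.1, missing_max = 0.1) {
  if (!is.matrix(dosages) || nrow(dosages) < 1L || ncol(dosages) < 1L) {
    stop("argument error: dosages must be a non-empty samples x markers matrix")
  }
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  nm <- colnames(dosages)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(dosages)))
  miss <- colMeans(is.na(dosages))
  f <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0   # all-missing marker
  fail_maf <- maf < maf_min
  fail_mis <- miss > missing_max
  reason <- rep("", ncol(dosages))
  reason[fail_maf] <- "maf"
  reason[fail_mis] <- "missing"
  reason[fail_maf & fail_mis] <- "maf+missing"
  audit <- data.frame(marker = nm, maf = unname(maf),
                      missing_frac = unname(miss),
                      retained = !(fail_maf | fail_mis),
                      reason = reason, stringsAsFactors = FALSE)
  list(keep = nm[audit$retained], audit = audit)
}

#' Score SNPs by regression of expected allele counts on pool intensities
#'
#' For each marker, ordinary least squares with the serology-expected
#' B-allele count of each pool as response and the pool's intensity as
#' explanatory variable; the score is the coefficient of determination,
#' equal to the squared Pearson correlation. A marker with fewer than 3
#' usable pools or zero variance in either variable scores 0 and is flagged
#' degenerate. Missing intensities drop the pool from that marker's
#' regression.
#'
#' @param expected_counts Integer vector (one per pool) in `{0, 1, 2}`,
#'   derived from serology, never from array data.
#' @param intensities Numeric pools x markers matrix (or a vector for a
#'   single marker).
#' @return Data frame `marker_id`, `r_squared`, `n_obs`, `degenerate`.
#' @export
score_snp_regression <- function(expected_counts, intensities) {
  if (is.null(dim(intensities))) {
    intensities <- matrix(intensities, ncol = 1,
                          dimnames = list(NULL, "marker"))
  }
  stopifnot(length(expected_counts) == nrow(intensities))
  nm <- colnames(intensities)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(intensities)))
  res <- vapply(seq_len(ncol(intensities)), function(j) {
    x <- intensities[, j]
    ok <- !is.na(x) & !is.na(expected_counts)
    n <- sum(ok)
    if (n < 3L) return(c(0, n, 1))
    xs <- x[ok]; ys <- expected_counts[ok]
    if (stats::var(xs) == 0 || stats::var(ys) == 0) return(c(0, n, 1))
    c(stats::cor(xs, ys)^2, n, 0)
  }, numeric(3))
  data.frame(marker_id = nm, r_squared = res[1, ], n_obs = as.integer(res[2, ]),
             degenerate = res[3, ] == 1, stringsAsFactors = FALSE)
}

#' Association scan of a focal-allele count on individual genotypes
#'
#' Per marker, a linear trend regression of the response (the per-sample
#' focal-allele count, typically serology-derived) on the dosage, with a
#' two-sided F-test on the slope. Markers with zero dosage variance are
#' skipped with a message. Underflowing p-values are reported as the
#' smallest positive normalised double.
#'
#' @param dosages Numeric samples x markers matrix, entries `{0, 1, 2, NA}`.
#' @param response Numeric vector, one value per sample.
#' @return Data frame `marker_id`, `statistic` (F), `p_value`, `n`.
#' @export
association_scan <- function(dosages, response) {
  stopifnot(length(response) == nrow(dosages))
  if (stats::var(response, na.rm = TRUE) == 0) {
    stop("analysis error: response is constant")
  }
  nm <- colnames(dosages)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(dosages)))
  rows <- lapply(seq_len(ncol(dosages)), function(j) {
    x <- dosages[, j]
    ok <- !is.na(x) & !is.na(response)
    n <- sum(ok)
    if (n < 3L || stats::var(x[ok]) == 0) return(NULL)
    r <- stats::cor(x[ok], response[ok])
    r2 <- min(r^2, 1)
    Fstat <- if (r2 >= 1) Inf else r2 * (n - 2) / (1 - r2)
    p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
    if (p <= 0) p <- .Machine$double.xmin
    data.frame(marker_id = nm[j], statistic = Fstat, p_value = p,
               n = n, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0L) {
    message("association_scan: skipped ", skipped,
            " marker(s) with zero dosage variance or < 3 usable samples")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(marker_id = character(), statistic = numeric(),
                      p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Delimit the candidate region from per-marker scores
#'
#' A marker passes at `score >= threshold` (metric `"score"`, e.g. r2) or
#' `p <= threshold` (metric `"p"`). Within each chromosome, passing markers
#' are grouped into runs where consecutive passers are at most `max_gap_bp`
#' apart; the winning run is the one with the most passing markers, ties
#' broken by the higher peak score (smaller p), then by leftmost position.
#' The region is the smallest interval covering the winning run.
#'
#' @param scores Data frame with `marker_id`, `chrom`, `pos`, and either a
#'   score column (`r_squared` by default) or `p_value`.
#' @param threshold Passing threshold (default 0.8 on r2).
#' @param max_gap_bp Maximum gap between consecutive passing markers.
#' @param metric `"score"` (higher is better) or `"p"` (lower is better).
#' @param score_col Column holding the score when `metric = "score"`.
#' @param genes Optional gene annotation (`gene_id`, `chrom`, `start`,
#'   `end`) intersected with the region.
#' @return List `chrom`, `start`, `end`, `markers`, `peak_marker`,
#'   `peak_value`, `genes` (character vector), `empty` (logical). An empty
#'   region (no passing marker) has `empty = TRUE`, not an error.
#' @export
detect_region <- function(scores, threshold = 0.8, max_gap_bp = 1e6,
                          metric = c("score", "p"), score_col = "r_squared",
                          genes = NULL) {
  metric <- match.arg(metric)
  val <- if (metric == "score") scores[[score_col]] else scores[["p_value"]]
  if (is.null(val)) stop("score column not found")
  pass <- if (metric == "score") val >= threshold else val <= threshold
  pass[is.na(pass)] <- FALSE
  empty <- list(chrom = NA_character_, start = NA_integer_, end = NA_integer_,
                markers = character(), peak_marker = NA_character_,
                peak_value = NA_real_, genes = character(), empty = TRUE)
  if (!any(pass)) return(empty)
  ps <- scores[pass, , drop = FALSE]
  better <- function(a, b) if (metric == "score") a > b else a < b
  best <- NULL
  for (ch in unique(ps$chrom)) {
    sub <- ps[ps$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    gaps <- diff(sub$pos)
    run_id <- cumsum(c(0L, as.integer(gaps > max_gap_bp)))
    for (r in unique(run_id)) {
      m <- sub[run_id == r, , drop = FALSE]
      v <- if (metric == "score") m[[score_col]] else m[["p_value"]]
      peak_i <- if (metric == "score") which.max(v) else which.min(v)
      cand <- list(chrom = ch, start = min(m$pos), end = max(m$pos),
                   markers = m$marker_id, peak_marker = m$marker_id[peak_i],
                   peak_value = v[peak_i], n = nrow(m))
      if (is.null(best) ||
          cand$n > best$n ||
          (cand$n == best$n && better(cand$peak_value, best$peak_value)) ||
          (cand$n == best$n && cand$peak_value == best$peak_value &&
           cand$start < best$start)) {
        best <- cand
      }
    }
  }
  best$n <- NULL
  best$genes <- character()
  if (!is.null(genes)) {
    hit <- genes$chrom == best$chrom & genes$start <= best$end &
      genes$end >= best$start
    best$genes <- genes$gene_id[hit]
  }
  best$empty <- FALSE
  best
}

#' Manhattan-style plot of per-marker scores
#'
#' @param scores Data frame with `pos` and a value column.
#' @param value Column to plot (`r_squared` or `p_value`; p-values are drawn
#'   as -log10).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_scores <- function(scores, value = "r_squared", ...) {
  y <- scores[[value]]
  ylab <- value
  if (value == "p_value") {
    y <- -log10(y)
    ylab <- "-log10(p)"
  }
  graphics::plot(scores$pos / 1e6, y, pch = 16, cex = 0.4,
                 xlab = "position (Mb)", ylab = ylab, ...)
}
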