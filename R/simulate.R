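# Synthetic-data generator: line populations under Hardy-Weinberg, pedigree
# matings, serology observation with heterozygote-only error, array-intensity
# and DNA-pool simulation. The generator gives every downstream stage known
# truth, since the original study data are proprietary.

# Run code under a given RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-stage seeds derived from one master seed by fixed offsets.
.stage_seed <- function(seed, stage) {
  offsets <- c(population = 101L, mate = 211L, serology = 307L,
               intensity = 401L, pools = 503L, variants = 601L,
               gwas = 701L, scan = 809L, phase = 907L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% 2000000011L
}

#' Build and validate a simulation configuration
#'
#' Defines the study conditions the generator emulates: a set of breeding
#' lines with haplotype frequencies over a registry, pool sizes of 3 to 8
#' samples, array-intensity noise, heterozygote-only serology error, and a
#' causal region containing the causal gene plus decoy genes.
#'
#' @param seed Master integer seed; all stages derive their own seeds from it
#'   by fixed offsets.
#' @param lines Data frame with columns `line_id`, `breed`, `status`
#'   (`"fixed"`, `"segregating"` or `"unknown"`) and a list-column `freqs` of
#'   named numeric vectors (haplotype label -> frequency, summing to 1).
#' @param n_individuals Individuals sampled per line.
#' @param registry_labels Character vector of valid haplotype labels.
#' @param pool_sizes Allowed pool sizes; must lie in 3..8.
#' @param intensity_noise_sd,pool_noise_sd Gaussian noise on member and pool
#'   intensities (B-signal-fraction scale).
#' @param serology_het_error Probability that a serological heterozygote is
#'   reported with only one allele correct.
#' @param n_background_snps Unlinked background SNPs for the pooled scan.
#' @param causal_region List `(chrom, start, end)` of the candidate region.
#' @param causal_gene Gene id carrying the causal missense variants.
#' @param decoy_genes Data frame `gene_id`, `membrane` (logical),
#'   `tracks_serology` (logical) for constructed decoys.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       lines,
                       n_individuals = 50L,
                       registry_labels = load_panel_fixture()$registry$label,
                       pool_sizes = 3:8,
                       intensity_noise_sd = 0.05,
                       pool_noise_sd = 0.01,
                       serology_het_error = 0.1,
                       n_background_snps = 2000L,
                       causal_region = list(chrom = "1", start = 129700000L,
                                            end = 131400000L),
                       causal_gene = "CD99",
                       decoy_genes = data.frame(
                         gene_id = c("MEMDECOY1", "PATDECOY1"),
                         membrane = c(TRUE, FALSE),
                         tracks_serology = c(FALSE, TRUE))) {
  stopifnot(is.data.frame(lines),
            all(c("line_id", "breed", "status", "freqs") %in% colnames(lines)))
  for (i in seq_len(nrow(lines))) {
    f <- lines$freqs[[i]]
    if (abs(sum(f) - 1) > 1e-9) {
      stop("configuration error: frequencies for line ", lines$line_id[i],
           " sum to ", sum(f), ", not 1")
    }
    if (any(f < 0 | f > 1)) {
      stop("configuration error: frequency outside [0,1] in line ",
           lines$line_id[i])
    }
    unknown <- setdiff(names(f), registry_labels)
    if (length(unknown)) {
      stop("configuration error: unknown haplotype label(s) ",
           paste(unknown, collapse = ", "), " in line ", lines$line_id[i])
    }
  }
  if (any(pool_sizes < 3L | pool_sizes > 8L)) {
    stop("configuration error: pool sizes must lie in [3, 8]")
  }
  for (p in c(serology_het_error)) {
    if (p < 0 || p > 1) stop("configuration error: probability outside [0,1]")
  }
  if (intensity_noise_sd < 0 || pool_noise_sd < 0) {
    stop("configuration error: noise sd must be nonnegative")
  }
  if (causal_region$start > causal_region$end) {
    stop("configuration error: causal region start > end")
  }
  structure(list(seed = as.integer(seed), lines = lines,
                 n_individuals = as.integer(n_individuals),
                 registry_labels = registry_labels,
                 pool_sizes = as.integer(pool_sizes),
                 intensity_noise_sd = intensity_noise_sd,
                 pool_noise_sd = pool_noise_sd,
                 serology_het_error = serology_het_error,
                 n_background_snps = as.integer(n_background_snps),
                 causal_region = causal_region,
                 causal_gene = causal_gene,
                 decoy_genes = decoy_genes),
            class = "sim_config")
}

#' Default demonstration configuration mirroring the study's line inventory
#'
#' Eleven lines: an inbred line fixed for D1, five elite White Leghorn lines
#' (two fixed for D3, three segregating), one Rhode Island Red and two White
#' Plymouth Rock lines with no serology, a divergently selected antibody
#' line, and one synthetic conservation line carrying the two serology-less
#' haplotypes (H05, H09).
#' Frequencies are chosen so that the common haplotypes (H01, H03) dominate
#' and the reference-genome haplotype H06 is rare, as observed in elite
#' layers; every one of the 11 registry haplotypes segregates somewhere.
#'
#' @param seed Master seed.
#' @param n_individuals Individuals per line.
#' @return A `sim_config`.
#' @export
demo_config <- function(seed = 1L, n_individuals = 50L) {
  L <- function(id, breed, status, ...) {
    list(line_id = id, breed = breed, status = status, freqs = c(...))
  }
  specs <- list(
    L("IAH7", "WL",  "fixed",       `CD99-H01` = 1.0),
    L("WL1",  "WL",  "segregating", `CD99-H02` = 0.35, `CD99-H03` = 0.65),
    L("WL2",  "WL",  "fixed",       `CD99-H03` = 1.0),
    L("WL3",  "WL",  "segregating", `CD99-H01` = 0.40, `CD99-H03` = 0.55,
                                    `CD99-H06` = 0.05),
    L("WL4",  "WL",  "segregating", `CD99-H01` = 0.45, `CD99-H03` = 0.55),
    L("WL5",  "WL",  "fixed",       `CD99-H03` = 1.0),
    L("RIR1", "RIR", "unknown",     `CD99-H04` = 0.40, `CD99-H07` = 0.35,
                                    `CD99-H08` = 0.25),
    L("WPR1", "WPR", "unknown",     `CD99-H04` = 0.60, `CD99-H10` = 0.40),
    L("WPR2", "WPR", "unknown",     `CD99-H01` = 0.55, `CD99-H11` = 0.45),
    L("HAS",  "WL",  "segregating", `CD99-H01` = 0.50, `CD99-H03` = 0.45,
                                    `CD99-H06` = 0.05),
    L("CONS1", "synthetic", "unknown", `CD99-H05` = 0.50, `CD99-H09` = 0.50)
  )
  lines <- data.frame(
    line_id = vapply(specs, `[[`, "", "line_id"),
    breed = vapply(specs, `[[`, "", "breed"),
    status = vapply(specs, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  lines$freqs <- lapply(specs, `[[`, "freqs")
  sim_config(seed = seed, lines = lines, n_individuals = n_individuals)
}

#' Sample line populations under Hardy-Weinberg equilibrium
#'
#' Each individual's diplotype is two independent draws from its line's
#' haplotype frequency vector.
#'
#' @param config A `sim_config`.
#' @return Data frame `individual_id`, `line_id`, `hap1`, `hap2`, `sire_id`,
#'   `dam_id` (founders have `NA` parents).
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.stage_seed(config$seed, "population"), {
    out <- lapply(seq_len(nrow(config$lines)), function(i) {
      id <- config$lines$line_id[i]
      f <- config$lines$freqs[[i]]
      n <- config$n_individuals
      h1 <- sample(names(f), n, replace = TRUE, prob = f)
      h2 <- sample(names(f), n, replace = TRUE, prob = f)
      data.frame(individual_id = sprintf("%s_%03d", id, seq_len(n)),
                 line_id = id, hap1 = h1, hap2 = h2,
                 sire_id = NA_character_, dam_id = NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Mate two individuals
#'
#' Each progeny receives one uniformly chosen haplotype from each parent,
#' independently.
#'
#' @param sire,dam Single-row data frames (or lists) with `individual_id`,
#'   `hap1`, `hap2`.
#' @param n_progeny Number of progeny (>= 1).
#' @param seed Integer seed.
#' @param line_id Line id recorded for the progeny.
#' @return Data frame of progeny in the same shape as [sample_population()].
#' @export
mate <- function(sire, dam, n_progeny, seed, line_id = "cross") {
  if (n_progeny < 1) stop("argument error: n_progeny must be >= 1")
  for (p in list(sire, dam)) {
    if (is.na(p$hap1) || is.na(p$hap2)) stop("parent lacks a diplotype")
  }
  .with_seed(seed, {
    from_sire <- ifelse(stats::runif(n_progeny) < 0.5, sire$hap1, sire$hap2)
    from_dam  <- ifelse(stats::runif(n_progeny) < 0.5, dam$hap1, dam$hap2)
    data.frame(individual_id = sprintf("%s_%s_%03d", sire$individual_id,
                                       dam$individual_id, seq_len(n_progeny)),
               line_id = line_id, hap1 = from_sire, hap2 = from_dam,
               sire_id = sire$individual_id, dam_id = dam$individual_id,
               stringsAsFactors = FALSE)
  })
}

#' Observe serology with heterozygote-only error
#'
#' Translates each individual's diplotype through the haplotype-to-allele map
#' and applies the error model seen in alloantisera typing: homozygotes are
#' always reported correctly; with probability `het_error` a serological
#' heterozygote is reported as apparently homozygous for one (uniformly
#' chosen) of its two true alleles, i.e. the second allele is dropped or
#' replaced by the first. A record's alleles are therefore never disjoint
#' from the truth.
#'
#' @param pop Population data frame (`individual_id`, `line_id`, `hap1`,
#'   `hap2`).
#' @param map Named character vector, haplotype label -> serological allele.
#' @param het_error Error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame `individual_id`, `line_id`, `allele1`, `allele2`,
#'   `partial` (always `FALSE` here; the generator emits fully resolved
#'   records).
#' @export
observe_serology <- function(pop, map, het_error, seed) {
  unmapped <- setdiff(unique(c(pop$hap1, pop$hap2)), names(map))
  unmapped <- c(unmapped, names(map)[is.na(map)][names(map)[is.na(map)] %in%
                                                   c(pop$hap1, pop$hap2)])
  if (length(unmapped)) {
    stop("mapping error: no serological allele for haplotype(s) ",
         paste(unique(unmapped), collapse = ", "))
  }
  .with_seed(seed, {
    a1 <- unname(map[pop$hap1])
    a2 <- unname(map[pop$hap2])
    het <- a1 != a2
    err <- het & stats::runif(nrow(pop)) < het_error
    keep_first <- stats::runif(nrow(pop)) < 0.5
    obs1 <- ifelse(err, ifelse(keep_first, a1, a2), pmin(a1, a2))
    obs2 <- ifelse(err, obs1, pmax(a1, a2))
    data.frame(individual_id = pop$individual_id, line_id = pop$line_id,
               allele1 = pmin(obs1, obs2), allele2 = pmax(obs1, obs2),
               partial = FALSE, stringsAsFactors = FALSE)
  })
}

#' Simulate array intensities from allele dosages
#'
#' The intensity of a sample at a marker is modelled as the B-signal
#' fraction: dosage/2 plus Gaussian noise, truncated to `[0, 1]`. Missing
#' dosages give missing intensities.
#'
#' @param dosages Vector or matrix with entries in `{0, 1, 2, NA}`.
#' @param noise_sd Nonnegative Gaussian noise sd.
#' @param seed Integer seed.
#' @return Numeric object of the same shape as `dosages`.
#' @export
simulate_intensity <- function(dosages, noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  .with_seed(seed, {
    x <- dosages / 2 + stats::rnorm(length(dosages), 0, noise_sd)
    x <- pmin(pmax(x, 0), 1)
    x[is.na(dosages)] <- NA_real_
    if (is.matrix(dosages)) {
      x <- matrix(x, nrow(dosages), dimnames = dimnames(dosages))
    }
    x
  })
}

#' Pool member intensities
#'
#' A pool's intensity at each marker is the mean of its members' intensities
#' (equimolar DNA assumed) plus Gaussian pool-level noise, truncated to
#' `[0, 1]`.
#'
#' @param member_intensity Matrix (members x markers).
#' @param pool_assign Factor/character of pool ids, one per member row.
#' @param pool_noise_sd Pool-level Gaussian noise sd.
#' @param seed Integer seed.
#' @return Matrix (pools x markers), rows in `sort(unique(pool_assign))`
#'   order.
#' @export
pool_intensities <- function(member_intensity, pool_assign, pool_noise_sd,
                             seed) {
  pools <- sort(unique(as.character(pool_assign)))
  m <- t(vapply(pools, function(p) {
    colMeans(member_intensity[pool_assign == p, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(member_intensity))))
  .with_seed(seed, {
    m <- m + stats::rnorm(length(m), 0, pool_noise_sd)
    pmin(pmax(m, 0), 1)
  })
}

#' Convert diplotypes to dosage genotypes over a marker panel
#'
#' @param pop Population data frame with `hap1`, `hap2` labels.
#' @param registry,panel Registry and panel defining the allele vectors.
#' @return Integer matrix (individuals x assays) of alt-allele dosages.
#' @export
panel_genotypes <- function(pop, registry, panel) {
  alt <- hap_alt_matrix(registry, panel)
  bad <- setdiff(unique(c(pop$hap1, pop$hap2)), rownames(alt))
  if (length(bad)) stop("unknown haplotype label(s): ",
                        paste(bad, collapse = ", "))
  g <- alt[pop$hap1, , drop = FALSE] + alt[pop$hap2, , drop = FALSE]
  rownames(g) <- pop$individual_id
  g
}

#' Simulate a pooled-GWAS study
#'
#' Emulates the pooled design used to map a biallelic alloantigen: two
#' pedigree families from sire x dam matings both heterozygous for the two
#' focal alleles, plus one set of non-pedigree birds, each contributing three
#' DNA pools of serologically identical individuals (expected B-allele counts
#' 0, 1 and 2), with 3 to 8 members per pool. The causal SNP's member dosage
#' is the diplotype's count of the `hapB` haplotype; background SNPs draw a
#' uniform minor-allele frequency in `[0.1, 0.5]` and binomial dosages
#' independent of serology.
#'
#' @param config A `sim_config` (supplies noise levels, pool sizes and the
#'   number of background SNPs).
#' @param hapA,hapB Haplotype labels for the two focal alleles (A and B).
#' @param n_progeny Progeny generated per family before pools are drawn.
#' @param seed Seed overriding the config-derived one (used for replicate
#'   loops).
#' @return List: `pools` (data frame `pool_id`, `expected_count`, `size`),
#'   `intensity` (pools x markers matrix), `markers` (data frame `marker_id`,
#'   `chrom`, `pos`), `causal_marker`, `member_dosage` (members x markers).
#' @export
simulate_pool_study <- function(config, hapA = "CD99-H01", hapB = "CD99-H02",
                                n_progeny = 40L,
                                seed = .stage_seed(config$seed, "pools")) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    par_row <- function(id, h1, h2) {
      data.frame(individual_id = id, line_id = "NIU", hap1 = h1, hap2 = h2,
                 sire_id = NA, dam_id = NA, stringsAsFactors = FALSE)
    }
    fam_seeds <- sample.int(1e9, 3)
    members <- list()
    for (f in 1:2) {
      sire <- par_row(sprintf("S%d", f), hapA, hapB)
      dam <- par_row(sprintf("D%d", f), hapA, hapB)
      fam <- mate(sire, dam, n_progeny, fam_seeds[f],
                  line_id = sprintf("FAM%d", f))
      # the family must yield enough typed progeny in every serological
      # class to fill a pool; hatch further batches if a class runs short
      batch <- 1L
      repeat {
        dose <- (fam$hap1 == hapB) + (fam$hap2 == hapB)
        if (all(table(factor(dose, 0:2)) >= min(config$pool_sizes)) ||
            batch >= 20L) break
        batch <- batch + 1L
        more <- mate(sire, dam, n_progeny, fam_seeds[f] + batch,
                     line_id = sprintf("FAM%d", f))
        more$individual_id <- paste0(more$individual_id, "b", batch)
        fam <- rbind(fam, more)
      }
      members[[f]] <- fam
    }
    # non-pedigree set: unrelated birds assembled per serological class
    # (pools were built from individuals already typed as AA, AB or BB)
    per_class <- max(config$pool_sizes)
    np_h1 <- rep(c(hapA, hapA, hapB), each = per_class)
    np_h2 <- rep(c(hapA, hapB, hapB), each = per_class)
    n3 <- length(np_h1)
    members[[3]] <- data.frame(
      individual_id = sprintf("NP_%03d", seq_len(n3)), line_id = "NP",
      hap1 = np_h1, hap2 = np_h2,
      sire_id = NA_character_, dam_id = NA_character_,
      stringsAsFactors = FALSE)

    pool_rows <- list(); pool_members <- list()
    for (s in 1:3) {
      pop <- members[[s]]
      dose <- (pop$hap1 == hapB) + (pop$hap2 == hapB)
      for (k in 0:2) {
        avail <- which(dose == k)
        size <- sample(config$pool_sizes, 1)
        if (length(avail) < min(config$pool_sizes)) {
          stop("simulation error: fewer than 3 individuals with expected ",
               "count ", k, " in set ", s, "; increase n_progeny")
        }
        size <- min(size, length(avail))
        take <- sample(avail, size)
        pid <- sprintf("SET%d_E%d", s, k)
        pool_rows[[pid]] <- data.frame(pool_id = pid, expected_count = k,
                                       size = size, stringsAsFactors = FALSE)
        pool_members[[pid]] <- pop[take, ]
      }
    }
    pools <- do.call(rbind, pool_rows)
    rownames(pools) <- NULL
    allmem <- do.call(rbind, pool_members)
    assign_id <- rep(pools$pool_id, times = pools$size)

    n_bg <- config$n_background_snps
    n_mem <- nrow(allmem)
    maf <- stats::runif(n_bg, 0.1, 0.5)
    bg <- vapply(maf, function(f) stats::rbinom(n_mem, 2, f),
                 integer(n_mem))
    causal <- (allmem$hap1 == hapB) + (allmem$hap2 == hapB)
    dosage <- cbind(bg, causal)
    marker_id <- c(sprintf("BG%05d", seq_len(n_bg)), "CAUSAL")
    colnames(dosage) <- marker_id
    # causal SNP sits inside the causal gene's simulated span (first slot of
    # the candidate region; see simulate_variant_table)
    causal_pos <- as.integer(config$causal_region$start + 6000L)
    pos <- c(sort(sample(setdiff(seq(1e6, 196e6, by = 1e3),
                                 causal_pos), n_bg)), causal_pos)
    markers <- data.frame(marker_id = marker_id, chrom = "1", pos = pos,
                          stringsAsFactors = FALSE)

    sub_seeds <- sample.int(1e9, 2)
    mem_int <- simulate_intensity(dosage, config$intensity_noise_sd,
                                  sub_seeds[1])
    pool_int <- pool_intensities(mem_int, assign_id, config$pool_noise_sd,
                                 sub_seeds[2])
    pool_int <- pool_int[pools$pool_id, , drop = FALSE]
    list(pools = pools, intensity = pool_int, markers = markers,
         causal_marker = "CAUSAL", member_dosage = dosage)
  })
}
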