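# Haplotype -> serological allele mapping and concordance auditing.

dip <- function(...) {
  rows <- list(...)
  data.frame(individual_id = vapply(rows, `[[`, "", 1),
             hap1 = vapply(rows, `[[`, "", 2),
             hap2 = vapply(rows, `[[`, "", 3), stringsAsFactors = FALSE)
}
sero <- function(...) {
  rows <- list(...)
  data.frame(individual_id = vapply(rows, `[[`, "", 1),
             allele1 = vapply(rows, `[[`, "", 2),
             allele2 = vapply(rows, function(r)
               if (length(r) >= 3 && !is.na(r[[3]])) r[[3]] else NA_character_,
               character(1)),
             partial = vapply(rows, function(r)
               isTRUE(length(r) >= 4 && r[[4]]), logical(1)),
             stringsAsFactors = FALSE)
}

test_that("fixed haplotype-monomorphic lines anchor the map", {
  prof <- mk_profiles(list("WL2", "fixed", "D3"),
                      list("WL5", "fixed", "D3"),
                      list("MIX", "fixed", "D9"),
                      list("WL1", "segregating", c("D2", "D3")))
  lh <- list(WL2 = "CD99-H03", WL5 = "CD99-H03",
             MIX = c("CD99-H07", "CD99-H08"),
             WL1 = c("CD99-H02", "CD99-H03"))
  map <- anchor_map(prof, lh)
  # two independent anchors merge into one entry; a 2-haplotype fixed line
  # contributes nothing
  expect_equal(map$haplotype, "CD99-H03")
  expect_equal(map$allele, "D3")
  expect_equal(map$provenance, "anchor")
  # conflicting anchors are a hard error
  prof2 <- mk_profiles(list("A", "fixed", "D3"), list("B", "fixed", "D1"))
  lh2 <- list(A = "CD99-H03", B = "CD99-H03")
  expect_error(anchor_map(prof2, lh2), "conflicting")
})

test_that("co-segregation extends the map and reports ties honestly", {
  map0 <- data.frame(haplotype = "CD99-H03", allele = "D3",
                     provenance = "anchor", stringsAsFactors = FALSE)
  # one unmapped haplotype against one unmapped name in a segregating line
  d <- dip(list("i1", "CD99-H02", "CD99-H03"),
           list("i2", "CD99-H03", "CD99-H03"),
           list("i3", "CD99-H02", "CD99-H02"))
  s <- sero(list("i1", "D2", "D3"), list("i2", "D3", "D3"),
            list("i3", "D2", "D2"))
  map <- cosegregation_extend(map0, d, s)
  expect_equal(map$allele[map$haplotype == "CD99-H02"], "D2")
  expect_equal(map$provenance[map$haplotype == "CD99-H02"], "cosegregation")

  # symmetric evidence: two haplotypes, two names, no individual separates
  # them -> tie, nothing guessed
  d2 <- dip(list("j1", "CD99-H07", "CD99-H08"))
  s2 <- sero(list("j1", "D7", "D8"))
  expect_message(map2 <- cosegregation_extend(map0, d2, s2), "tied")
  expect_true(attr(map2, "tie"))
  expect_false(any(c("CD99-H07", "CD99-H08") %in% map2$haplotype))

  # anchors are never overwritten
  expect_true(all(map$allele[map$provenance == "anchor"] == "D3"))
})

test_that("protein-class inheritance maps H06 like H03", {
  cls_list <- protein_classes(fx$registry, fx$panel)
  classes <- stats::setNames(rep(names(cls_list), lengths(cls_list)),
                             unlist(cls_list))
  map0 <- data.frame(haplotype = "CD99-H03", allele = "D3",
                     provenance = "anchor", stringsAsFactors = FALSE)
  d <- dip(list("i1", "CD99-H03", "CD99-H06"))
  s <- sero(list("i1", "D3", "D3"))
  map <- cosegregation_extend(map0, d, s, classes = classes)
  expect_equal(map$allele[map$haplotype == "CD99-H06"], "D3")
  expect_equal(map$provenance[map$haplotype == "CD99-H06"], "protein-class")
})

test_that("simulated three-allele line recovers the true map", {
  truth <- c(`CD99-H01` = "D1", `CD99-H02` = "D2", `CD99-H03` = "D3")
  specs <- list(list("FIX3", "fixed", c(`CD99-H03` = 1.0)),
                list("SEG", "segregating",
                     c(`CD99-H01` = 0.3, `CD99-H02` = 0.3, `CD99-H03` = 0.4)))
  lines <- data.frame(line_id = c("FIX3", "SEG"), breed = "WL",
                      status = c("fixed", "segregating"),
                      stringsAsFactors = FALSE)
  lines$freqs <- lapply(specs, `[[`, 3)
  cfg <- sim_config(seed = 77, lines = lines, n_individuals = 200L,
                    serology_het_error = 0.05)
  pop <- sample_population(cfg)
  obs <- observe_serology(pop, truth, cfg$serology_het_error,
                          seed = 1234)
  prof <- line_profiles(cfg)
  lh <- lapply(split(pop, pop$line_id), function(p) unique(c(p$hap1, p$hap2)))
  map <- anchor_map(prof, lh)
  d <- pop[, c("individual_id", "hap1", "hap2")]
  map <- cosegregation_extend(map, d, obs)
  got <- stats::setNames(map$allele, map$haplotype)[names(truth)]
  expect_equal(unname(got), unname(truth))
})

test_that("concordance compares unordered pairs and classifies errors", {
  map <- data.frame(haplotype = c("CD99-H01", "CD99-H02", "CD99-H03"),
                    allele = c("D1", "D2", "D3"),
                    provenance = "anchor", stringsAsFactors = FALSE)
  d <- dip(list("i1", "CD99-H01", "CD99-H03"),
           list("i2", "CD99-H03", "CD99-H01"),
           list("i3", "CD99-H01", "CD99-H03"),
           list("i4", "CD99-H03", "CD99-H03"),
           list("i5", "CD99-H01", "CD99-H03"),
           list("i6", "CD99-H01", "CD99-H02"))
  s <- sero(list("i1", "D1", "D3"),
            list("i2", "D1", "D3"),          # order-insensitive agreement
            list("i3", "D1", "D1"),          # second allele wrong
            list("i4", "D2", "D3"),          # homozygote misidentified
            list("i5", "D1"),                # single antigen: missed
            list("i6", "D2", "D3", TRUE))    # partial "D2 and/or D3"
  rep <- concordance(map, d, s)
  expect_equal(rep$n_total, 6L)
  expect_equal(rep$n_agree, 2L)
  # i3 and the incompatible partial i6 both share exactly one allele
  expect_equal(unname(rep$classes["second_allele_wrong"]), 2L)
  expect_equal(unname(rep$classes["homozygote_misidentified"]), 1L)
  expect_equal(unname(rep$classes["second_allele_missed"]), 1L)
  expect_equal(unname(rep$classes["both_alleles_wrong"]), 0L)
  expect_equal(sum(rep$classes), rep$n_total - rep$n_agree)
  # unmapped haplotype names the individual
  d2 <- dip(list("zz", "CD99-H07", "CD99-H01"))
  s2 <- sero(list("zz", "D1", "D1"))
  expect_error(concordance(map, d2, s2), "zz")
})

test_that("partial records agree when any completion matches", {
  map <- data.frame(haplotype = c("CD99-H02", "CD99-H03"),
                    allele = c("D2", "D3"), provenance = "anchor",
                    stringsAsFactors = FALSE)
  d <- dip(list("i1", "CD99-H02", "CD99-H03"),
           list("i2", "CD99-H03", "CD99-H03"))
  s <- sero(list("i1", "D2", "D3", TRUE), list("i2", "D2", "D3", TRUE))
  rep <- concordance(map, d, s)
  expect_equal(rep$n_agree, 2L)
  expect_equal(rep$n_partial_agree, 2L)
})

test_that("het-only serology error shapes the concordance report", {
  truth <- c(`CD99-H01` = "D1", `CD99-H03` = "D3")
  lines <- data.frame(line_id = "SEG", breed = "WL", status = "segregating",
                      stringsAsFactors = FALSE)
  lines$freqs <- list(c(`CD99-H01` = 0.5, `CD99-H03` = 0.5))
  eps <- 0.1
  for (s in 1:5) {
    cfg <- sim_config(seed = 1000 + s, lines = lines,
                      n_individuals = 10000L, serology_het_error = eps)
    pop <- sample_population(cfg)
    obs <- observe_serology(pop, truth, eps, seed = 555 + s)
    map <- data.frame(haplotype = names(truth), allele = unname(truth),
                      provenance = "anchor", stringsAsFactors = FALSE)
    rep <- concordance(map, pop[, c("individual_id", "line_id",
                                    "hap1", "hap2")], obs)
    # homozygotes are never misidentified under the het-only error model
    expect_equal(unname(rep$classes["homozygote_misidentified"]), 0L)
    p_het <- mean(truth[pop$hap1] != truth[pop$hap2])
    expected <- 1 - eps * p_het
    se <- sqrt(expected * (1 - expected) / nrow(pop))
    expect_lt(abs(rep$fraction - expected), 3 * se)
  }
})
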