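# Synthetic-data generator: Hardy-Weinberg sampling, Mendelian matings,
# serology error model, intensity model, determinism.

mk_cfg <- function(seed, specs, n = 50L, ...) {
  lines <- data.frame(line_id = vapply(specs, `[[`, "", 1),
                      breed = "WL",
                      status = vapply(specs, `[[`, "", 2),
                      stringsAsFactors = FALSE)
  lines$freqs <- lapply(specs, `[[`, 3)
  sim_config(seed = seed, lines = lines, n_individuals = n, ...)
}

test_that("sample_population draws Hardy-Weinberg diplotypes per line", {
  # degenerate frequency: every individual is H03/H03
  cfg <- mk_cfg(1, list(list("F", "fixed", c(`CD99-H03` = 1.0))), n = 20L)
  pop <- sample_population(cfg)
  expect_true(all(pop$hap1 == "CD99-H03" & pop$hap2 == "CD99-H03"))

  # binomial oracle: heterozygote fraction for a 50/50 line is 0.5
  cfg2 <- mk_cfg(7, list(list("S", "segregating",
                              c(`CD99-H01` = 0.5, `CD99-H03` = 0.5))),
                 n = 10000L)
  pop2 <- sample_population(cfg2)
  het <- mean(pop2$hap1 != pop2$hap2)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)

  # bookkeeping: line partition is preserved
  cfg3 <- mk_cfg(2, list(list("A", "fixed", c(`CD99-H03` = 1.0)),
                         list("B", "fixed", c(`CD99-H01` = 1.0))), n = 10L)
  pop3 <- sample_population(cfg3)
  expect_equal(unname(table(pop3$line_id)[c("A", "B")]),
               c(10L, 10L), ignore_attr = TRUE)
  expect_true(all(pop3$hap1[pop3$line_id == "B"] == "CD99-H01"))
})

test_that("configuration errors are caught", {
  expect_error(mk_cfg(1, list(list("X", "fixed", c(`CD99-H03` = 0.9)))),
               "sum to")
  expect_error(mk_cfg(1, list(list("X", "fixed", c(NOPE = 1.0)))),
               "unknown haplotype")
  expect_error(mk_cfg(1, list(list("X", "fixed", c(`CD99-H03` = 1.0))),
                      pool_sizes = 2:4), "3, 8")
  expect_error(mk_cfg(1, list(list("X", "fixed", c(`CD99-H03` = 1.0))),
                      serology_het_error = 1.5), "probability")
})

test_that("mate transmits one haplotype per parent", {
  ind <- function(id, h1, h2) data.frame(individual_id = id, hap1 = h1,
                                         hap2 = h2, stringsAsFactors = FALSE)
  # fixed cross
  pr <- mate(ind("s", "CD99-H01", "CD99-H01"), ind("d", "CD99-H01", "CD99-H01"),
             10, seed = 1)
  expect_true(all(pr$hap1 == "CD99-H01" & pr$hap2 == "CD99-H01"))

  expect_error(mate(ind("s", "CD99-H01", "CD99-H01"),
                    ind("d", "CD99-H01", "CD99-H01"), 0, 1), "n_progeny")

  # Mendelian oracle: AB x AB gives 1:2:1 at alpha = 0.01
  pr2 <- mate(ind("s", "CD99-H01", "CD99-H02"),
              ind("d", "CD99-H01", "CD99-H02"), 4000, seed = 11)
  k <- table(factor(dip_key(pr2$hap1, pr2$hap2)))
  expect_equal(length(k), 3L)
  chi <- chisq.test(as.vector(k), p = c(1, 2, 1) / 4)
  expect_gt(chi$p.value, 0.01)

  # backcross support
  pr3 <- mate(ind("s", "CD99-H01", "CD99-H02"),
              ind("d", "CD99-H03", "CD99-H03"), 200, seed = 5)
  expect_true(all(dip_key(pr3$hap1, pr3$hap2) %in%
                    dip_key(c("CD99-H01", "CD99-H02"),
                            c("CD99-H03", "CD99-H03"))))
})

test_that("serology error is heterozygote-only and never disjoint", {
  map <- c(`CD99-H01` = "D1", `CD99-H02` = "D2", `CD99-H03` = "D3")
  hom <- data.frame(individual_id = "a", line_id = "L",
                    hap1 = "CD99-H03", hap2 = "CD99-H03")
  het <- data.frame(individual_id = "b", line_id = "L",
                    hap1 = "CD99-H01", hap2 = "CD99-H03")

  # homozygotes are reported correctly even at error 1
  for (s in 1:20) {
    r <- observe_serology(hom, map, het_error = 1, seed = s)
    expect_equal(c(r$allele1, r$allele2), c("D3", "D3"))
  }
  # error off: heterozygote exact
  r0 <- observe_serology(het, map, het_error = 0, seed = 1)
  expect_equal(c(r0$allele1, r0$allele2), c("D1", "D3"))
  # error 1: one allele correct, never an allele outside the true pair
  seen <- character()
  for (s in 1:40) {
    r1 <- observe_serology(het, map, het_error = 1, seed = s)
    expect_true(r1$allele1 == r1$allele2)
    expect_true(r1$allele1 %in% c("D1", "D3"))
    seen <- c(seen, r1$allele1)
  }
  expect_setequal(unique(seen), c("D1", "D3"))  # both drops occur
  # unmapped haplotype refused
  expect_error(observe_serology(het, map["CD99-H01"], 0, 1), "mapping error")
})

test_that("intensity model is linear in dosage with Gaussian noise", {
  expect_equal(simulate_intensity(c(0, 1, 2), 0, seed = 1), c(0, 0.5, 1))
  expect_true(is.na(simulate_intensity(c(NA, 2), 0, 1)[1]))
  # pool of dosages {0,1,2} without noise averages to 0.5
  mem <- simulate_intensity(matrix(c(0, 1, 2), 3, 1), 0, seed = 1)
  pool <- pool_intensities(mem, rep("p1", 3), 0, seed = 1)
  expect_equal(unname(pool[1, 1]), 0.5)
  # Gaussian oracle: sample sd within 5% of nominal (dosage 1 keeps the
  # draw away from the truncation boundaries)
  x <- simulate_intensity(rep(1L, 10000), 0.05, seed = 42)
  expect_lt(abs(sd(x) - 0.05) / 0.05, 0.05)
  expect_error(simulate_intensity(0:2, -0.1, 1), "nonnegative")
})

test_that("pool expected allele count equals mean member dosage", {
  cfg <- demo_config(seed = 9, n_individuals = 20)
  st <- simulate_pool_study(cfg)
  # reconstruct each pool's mean causal dosage from the member matrix
  assign_id <- rep(st$pools$pool_id, times = st$pools$size)
  for (p in st$pools$pool_id) {
    mean_dose <- mean(st$member_dosage[assign_id == p, "CAUSAL"])
    expect_equal(mean_dose,
                 st$pools$expected_count[st$pools$pool_id == p])
  }
  expect_true(all(st$pools$size >= 3 & st$pools$size <= 8))
})

test_that("generator output is reproducible for a fixed seed", {
  cfg <- demo_config(seed = 4, n_individuals = 15)
  expect_identical(sample_population(cfg), sample_population(cfg))
  expect_identical(simulate_pool_study(cfg), simulate_pool_study(cfg))
  expect_identical(simulate_variant_table(cfg), simulate_variant_table(cfg))
})

test_that("variant table reflects line fixation and allele identity", {
  cfg <- demo_config(seed = 2, n_individuals = 10)
  vt <- simulate_variant_table(cfg)
  causal <- vt$variants[vt$variants$gene_id == cfg$causal_gene, ]
  fixed <- vt$profiles$line_id[vt$profiles$status == "fixed"]
  # fixed lines carry no heterozygous calls anywhere in the causal gene
  expect_false(any(unlist(causal[fixed]) == "het"))
  # two lines fixed for the same allele have identical genotype columns
  d3_fixed <- vt$profiles$line_id[vt$profiles$status == "fixed" &
    vapply(vt$profiles$alleles, function(a) identical(a, "D3"), logical(1))]
  expect_gte(length(d3_fixed), 2L)
  expect_equal(causal[[d3_fixed[1]]], causal[[d3_fixed[2]]])
  # region too small for the requested genes is a configuration error
  cfg2 <- demo_config(seed = 2)
  cfg2$causal_region$end <- cfg2$causal_region$start + 1000L
  expect_error(simulate_variant_table(cfg2), "too small")
})
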