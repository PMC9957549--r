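# Candidate-gene screen: impact classes, membrane filter, line-consistency.

test_that("impact classification follows the sequence-ontology convention", {
  effects <- c("missense", "synonymous", "splice_region", "stop_gained",
               "frameshift", "intergenic", "intronic")
  expect_equal(classify_impact(effects),
               c("MODERATE", "LOW", "LOW", "HIGH", "HIGH", "MODIFIER",
                 "MODIFIER"))
  expect_error(classify_impact("nonsense_mediated"), "annotation error")
})

test_that("select_impactful keeps exactly HIGH and MODERATE", {
  v <- data.frame(id = letters[1:5],
                  impact = c("HIGH", "MODERATE", "LOW", "MODIFIER", "LOW"))
  expect_equal(select_impactful(v)$id, c("a", "b"))
  expect_equal(nrow(select_impactful(v[0, ])), 0L)
  # simulated table: the retained count equals the constructed count
  cfg <- demo_config(seed = 13, n_individuals = 10)
  vt <- simulate_variant_table(cfg)
  expect_equal(nrow(select_impactful(vt$variants)),
               sum(vt$variants$impact %in% c("HIGH", "MODERATE")))
})

test_that("membrane filter retains the five membrane genes of the region", {
  genes <- region_gene_fixture()
  expect_setequal(membrane_filter(genes)$gene_id,
                  c("ARSD", "ARSE", "CD99", "P2RY8", "SLC25A6"))
  # empty component set is excluded
  genes2 <- rbind(genes, data.frame(gene_id = "EMPTY", chrom = "1",
                                    start = 1L, end = 2L,
                                    cellular_components = ""))
  expect_false("EMPTY" %in% membrane_filter(genes2)$gene_id)
})

test_that("consistency checks mirror the line-level serology argument", {
  # three same-allele fixed lines, identical hom-alt columns: identity holds
  v <- data.frame(chrom = "1", pos = 1:2, id = c("v1", "v2"), ref = "G",
                  alt = "A", gene_id = "G1", effect = "missense",
                  impact = "MODERATE",
                  L1 = c("hom-alt", "hom-ref"), L2 = c("hom-alt", "hom-ref"),
                  L3 = c("hom-alt", "hom-ref"), L4 = c("hom-ref", "hom-alt"),
                  L5 = c("het", "hom-ref"),
                  stringsAsFactors = FALSE)
  prof <- mk_profiles(list("L1", "fixed", "D3"), list("L2", "fixed", "D3"),
                      list("L3", "fixed", "D3"), list("L4", "fixed", "D1"),
                      list("L5", "segregating", c("D1", "D3")))
  verdict <- consistency_check("G1", v, prof)
  expect_true(verdict$pass)
  expect_true(all(verdict$checks))

  # a het call in a fixed line breaks fixation
  v2 <- v; v2$L1[1] <- "het"
  expect_false(consistency_check("G1", v2, prof)$checks[["fixation_respected"]])

  # zero impactful variants: explicit failure reason
  v3 <- v; v3$impact <- "LOW"
  verdict3 <- consistency_check("G1", v3, prof)
  expect_false(verdict3$pass)
  expect_equal(verdict3$reason, "no-impactful-variants")

  # missing calls are ignored but counted
  v4 <- v; v4$L2[1] <- "missing"
  verdict4 <- consistency_check("G1", v4, prof)
  expect_true(verdict4$pass)
  expect_equal(verdict4$n_missing_ignored, 1L)
})

test_that("only the constructed causal gene survives both screens", {
  for (s in c(2, 17, 90)) {
    cfg <- demo_config(seed = s, n_individuals = 10)
    vt <- simulate_variant_table(cfg)
    rc <- rank_candidates(vt$genes, vt$variants, vt$profiles)
    expect_equal(rc$candidates$gene_id, cfg$causal_gene)
    # the audit reports every gene
    expect_setequal(rc$audit$gene_id, vt$genes$gene_id)
    # the pattern decoy passes consistency but is excluded as non-membrane
    expect_true(rc$audit$pass[rc$audit$gene_id == "PATDECOY1"])
    expect_false(rc$audit$membrane[rc$audit$gene_id == "PATDECOY1"])
    # the membrane decoy fails consistency
    expect_false(rc$audit$pass[rc$audit$gene_id == "MEMDECOY1"])
  }
})

test_that("all genes failing yields an empty candidate list with audit", {
  cfg <- demo_config(seed = 3, n_individuals = 10)
  vt <- simulate_variant_table(cfg)
  vt$genes$cellular_components <- "cytoplasm"   # nothing is membrane
  rc <- rank_candidates(vt$genes, vt$variants, vt$profiles)
  expect_equal(nrow(rc$candidates), 0L)
  expect_equal(nrow(rc$audit), nrow(vt$genes))
})

test_that("the screen is monotone in line profiles and order-invariant", {
  cfg <- demo_config(seed = 11, n_individuals = 10)
  vt <- simulate_variant_table(cfg)
  known <- vt$profiles[vt$profiles$status %in% c("fixed", "segregating"), ]
  full <- rank_candidates(vt$genes, vt$variants, vt$profiles)
  # adding profiles can only remove candidates: any gene passing with the
  # full set also passes with any 2+ line subset
  set.seed(99)
  for (k in 1:5) {
    idx <- sort(sample(nrow(known), sample(2:nrow(known), 1)))
    sub <- known[idx, , drop = FALSE]
    rc_sub <- rank_candidates(vt$genes, vt$variants, sub)
    passing_full <- full$audit$gene_id[full$audit$pass]
    passing_sub <- rc_sub$audit$gene_id[rc_sub$audit$pass]
    expect_true(all(passing_full %in% passing_sub))
  }
  # verdicts do not depend on variant row order
  shuffled <- vt$variants[sample(nrow(vt$variants)), ]
  rc_shuf <- rank_candidates(vt$genes, shuffled, vt$profiles)
  expect_equal(rc_shuf$audit[order(rc_shuf$audit$gene_id), ],
               full$audit[order(full$audit$gene_id), ],
               ignore_attr = TRUE)
})

test_that("variant tables round-trip through VCF", {
  cfg <- demo_config(seed = 6, n_individuals = 10)
  vt <- simulate_variant_table(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(vt$variants, path)
  back <- read_variant_vcf(path)
  line_ids <- vt$profiles$line_id
  expect_equal(back$gene_id, vt$variants$gene_id)
  expect_equal(back$impact, vt$variants$impact)
  for (l in line_ids) expect_equal(back[[l]], vt$variants[[l]])
  # screening the round-tripped table gives the same candidate
  rc <- rank_candidates(vt$genes, back, vt$profiles)
  expect_equal(rc$candidates$gene_id, cfg$causal_gene)
})
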