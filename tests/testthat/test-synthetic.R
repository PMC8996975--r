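test_that("generator validates designs and is deterministic", {
  expect_error(synthetic_design(probes_per_gene = 0), "probes_per_gene")
  expect_error(
    synthetic_design(planted_sets = list(list(name = "S",
                                              genes = "GENE0001",
                                              delta_log2 = 0,
                                              direction = "up"))),
    "unidentifiable")
  expect_error(
    synthetic_design(planted_sets = list(list(name = "S",
                                              genes = "GENE0001",
                                              delta_log2 = 1,
                                              direction = "sideways"))),
    "direction")
  d <- synthetic_design(n_genes = 50, probes_per_gene = 2, n_disease = 4,
                        n_control = 4, n_decoy_sets = 3, seed = 9)
  expect_identical(generate_cohort(d, "A"), generate_cohort(d, "A"))
})

test_that("null designs are exchangeable across the class split", {
  d <- synthetic_design(n_genes = 400, n_disease = 15, n_control = 15,
                        n_decoy_sets = 5, seed = 21)
  co <- generate_cohort(d, "A")
  m <- co$log2$values
  dis <- co$log2$phenotype == "disease"
  diffs <- rowMeans(m[, dis]) - rowMeans(m[, !dis])
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("planted truth is consistent with annotation and gene sets", {
  ps <- list(list(name = "UPSET", genes = sprintf("GENE%04d", 1:15),
                  delta_log2 = 1, direction = "up"),
             list(name = "DOWNSET", genes = sprintf("GENE%04d", 16:30),
                  delta_log2 = 1, direction = "down"))
  d <- synthetic_design(n_genes = 100, probes_per_gene = 3, n_disease = 5,
                        n_control = 5, planted_sets = ps, n_decoy_sets = 4,
                        seed = 2)
  co <- generate_cohort(d, "A")
  planted <- c(co$truth$up_genes, co$truth$down_genes)
  expect_setequal(co$truth$enriched_sets, c("UPSET", "DOWNSET"))
  expect_true(all(planted %in% co$annotation$gene_symbol))
  in_any_set <- unique(unlist(co$sets))
  expect_true(all(planted %in% in_any_set))
  # decoys avoid planted genes and match planted sizes
  decoys <- co$sets[grep("^DECOY", names(co$sets))]
  expect_length(decoys, 4)
  expect_true(all(lengths(decoys) == 15))
  expect_false(any(unlist(decoys) %in% planted))
  # the two tracks describe the same RNA: linear ~ 2^log2 up to unit-median noise
  ratio <- co$linear$values / 2^co$log2$values
  expect_lt(abs(median(log2(ratio))), 0.05)
})

test_that("a strongly planted set attains the smallest nominal p downstream", {
  ps <- list(list(name = "PLANTED", genes = sprintf("GENE%04d", 1:20),
                  delta_log2 = 2, direction = "up"))
  d <- synthetic_design(n_genes = 300, n_disease = 20, n_control = 20,
                        planted_sets = ps, n_decoy_sets = 15, seed = 1)
  co <- generate_cohort(d, "A")
  gm <- collapse_to_genes(co$log2, co$annotation)$matrix
  res <- gsea(gm, co$sets, gsea_config(n_permutations = 200, seed = 1))
  expect_equal(res$set[1], "PLANTED")
  expect_equal(res$nom_p[res$set == "PLANTED"], min(res$nom_p))
})

test_that("two-cohort generation enforces shared-gene consistency", {
  genes <- sprintf("GENE%04d", 1:50)
  mk <- function(dirn, seed)
    synthetic_design(n_genes = 50, n_disease = 4, n_control = 4,
                     planted_sets = list(list(name = paste0("S", seed),
                                              genes = genes[1:16],
                                              delta_log2 = 1,
                                              direction = dirn)),
                     n_decoy_sets = 2, seed = seed)
  expect_error(generate_two_cohorts(mk("up", 1), mk("down", 2),
                                    shared_genes = genes[1:3]),
               "inconsistent direction")
  both <- generate_two_cohorts(mk("up", 1), mk("up", 2),
                               shared_genes = genes[1:3])
  expect_equal(both$truth$shared_panel, sort(genes[1:3]))
  expect_identical(both$a$annotation, both$b$annotation)
  expect_identical(both$a$sets, both$b$sets)
  none <- generate_two_cohorts(mk("up", 1), mk("up", 2))
  expect_length(none$truth$shared_panel, 0)
})

test_that("qPCR fixture plants the requested DeltaDeltaCt shift", {
  fx0 <- generate_qpcr_fixture(n_per_group = 6, planted_log2_shift = 0,
                               seed = 5, sd_ct = 0.05)
  rq0 <- relative_expression(fx0, calibrator_group = "AC")
  expect_equal(exp(mean(log(rq0$rq[rq0$group != "AC"]))), 1, tolerance = 0.1)
  fx2 <- generate_qpcr_fixture(groups = c("AS", "LC"), n_per_group = 6,
                               planted_log2_shift = 2, seed = 5, sd_ct = 0.02)
  rq2 <- relative_expression(fx2, calibrator_group = "AS")
  expect_equal(exp(mean(log(rq2$rq[rq2$group == "LC"]))), 4, tolerance = 0.15)
  expect_identical(fx2, generate_qpcr_fixture(groups = c("AS", "LC"),
                                              n_per_group = 6,
                                              planted_log2_shift = 2,
                                              seed = 5, sd_ct = 0.02))
  expect_error(generate_qpcr_fixture(n_per_group = 2), "n_per_group")
})

test_that("survival fixture reflects its generative hazard structure", {
  expect_error(generate_survival_fixture(n = 10), "n must be")
  expect_error(generate_survival_fixture(hazard_ratio = 0), "hazard_ratio")
  # all events, no censoring: the KM curve reaches 0
  fx <- generate_survival_fixture(n = 60, hazard_ratio = 1, censor_rate = 0,
                                  seed = 3)
  expect_true(all(fx$event == 1))
  km <- km_estimate(fx)
  expect_equal(min(km$surv), 0)
  # planted hazard ratio is recovered by the O/E estimate
  fx3 <- generate_survival_fixture(n = 500, hazard_ratio = 3,
                                   censor_rate = 0.1, seed = 1)
  expect_gt(mean(fx3$event == 0), 0.02)   # censoring actually happens
  sp <- split_by_expression(fx3, "median")
  est <- logrank_hr(sp$high, sp$low)
  expect_gt(est$hr, 2); expect_lt(est$hr, 4.5)
  # bimodal marker: the median split recovers the generative groups exactly
  fb <- generate_survival_fixture(n = 100, hazard_ratio = 4, censor_rate = 0,
                                  seed = 2, separation = 10)
  spb <- split_by_expression(fb, "median")
  expect_true(all(spb$high$expression_value > 5))
  expect_true(all(spb$low$expression_value < 5))
})

test_that("null survival fixtures give well-behaved log-rank p-values", {
  ps <- vapply(1:20, function(s) {
    fx <- generate_survival_fixture(n = 80, hazard_ratio = 1,
                                    censor_rate = 0.1, seed = s)
    sp <- split_by_expression(fx, "median")
    logrank_hr(sp$high, sp$low)$p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 4)   # ~1 expected under the null
  expect_gt(mean(ps), 0.25)       # not systematically anti-conservative
})
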