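make_two_class <- function(vals_d, vals_c, genes) {
  m <- cbind(vals_d, vals_c)
  dimnames(m) <- list(genes, sprintf("s%02d", seq_len(ncol(m))))
  expr_matrix(m, "log2",
              rep(c("disease", "control"), c(ncol(vals_d), ncol(vals_c))))
}

test_that("signal-to-noise ranking applies the classical variance floor", {
  # mu_d = 2, mu_c = 1, sd = 0.5 each (floors 0.4/0.2 inactive) -> s = 1
  d <- matrix(2 + c(-0.5, 0.5) / sqrt(2), 1)
  c_ <- matrix(1 + c(-0.5, 0.5) / sqrt(2), 1)
  r <- rank_genes(make_two_class(d, c_, "G1"), absolute = FALSE)
  expect_equal(r$score, 1.0, tolerance = 1e-12)
  # constant gene: sigma = 0 both classes, floors 0.2|mu| kick in
  d2 <- matrix(5, 1, 3); c2 <- matrix(4, 1, 3)
  r2 <- rank_genes(make_two_class(d2, c2, "G1"), absolute = FALSE)
  expect_equal(r2$score, (5 - 4) / (0.2 * 5 + 0.2 * 4), tolerance = 1e-12)
  # random genes agree with the per-gene brute-force metric
  set.seed(7)
  X <- matrix(rnorm(50 * 8, 7), 50)
  em <- make_two_class(X[, 1:4], X[, 5:8], sprintf("G%02d", 1:50))
  r3 <- rank_genes(em, absolute = FALSE)
  want <- vapply(rownames(em$values),
                 function(g) brute_s2n(em$values[g, 1:4], em$values[g, 5:8]),
                 numeric(1))
  expect_equal(r3$score, unname(sort(want, decreasing = TRUE)),
               tolerance = 1e-12)
})

test_that("absolute mode ranks by |score| so strong down-regulation leads", {
  # diff metric makes the intended scores {+2, -3, +1} exact
  d <- matrix(c(6, 6, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  c_ <- matrix(c(4, 4, 4, 4, 4, 4), 3, 2, byrow = TRUE)
  em <- make_two_class(d, c_, c("UP2", "DOWN3", "UP1"))
  r <- rank_genes(em, absolute = TRUE, metric = "diff")
  expect_equal(r$gene, c("DOWN3", "UP2", "UP1"))
  expect_equal(r$score, c(3, 2, 1))
  expect_true(all(diff(r$score) <= 0))
})

test_that("enrichment score reproduces hand-enumerated running sums", {
  ranked <- structure(data.frame(gene = c("A", "B", "C", "D"),
                                 score = c(4, 3, 2, 1)),
                      absolute_mode = TRUE,
                      class = c("ranked_list", "data.frame"))
  top <- enrichment_score(ranked, "A", p = 0)
  expect_equal(top$es, 1.0)
  expect_equal(top$leading_edge, "A")
  mid <- enrichment_score(ranked, "B", p = 0)
  expect_equal(mid$running_sum, c(-1 / 3, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(mid$es, 2 / 3)
  expect_equal(mid$peak_rank, 2)
  st <- leading_edge_stats(top, N = 4)
  expect_equal(st$tag_pct, 1.0)
  expect_equal(st$gene_pct, 0.25)
  expect_equal(st$signal, 1 * 0.75 * 4 / 3)   # = 1.0
  expect_error(enrichment_score(ranked, c("A", "B", "C", "D")), "degenerate")
  expect_error(enrichment_score(ranked, "ZZZ"), "degenerate")
})

test_that("ES matches the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:60) {
    N <- sample(4:12, 1)
    genes <- sprintf("g%02d", 1:N)
    scores <- sort(abs(rnorm(N, sd = 2)), decreasing = TRUE)
    members <- sample(genes, sample(1:(N - 1), 1))
    p <- sample(c(0, 1, 2), 1)
    ranked <- structure(data.frame(gene = genes, score = scores),
                        absolute_mode = TRUE,
                        class = c("ranked_list", "data.frame"))
    got <- enrichment_score(ranked, members, p)
    want <- brute_es(genes, scores, members, p)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$running_sum, want$run, tolerance = 1e-12)
    expect_equal(got$running_sum[N], 0, tolerance = 1e-12)  # always closes
  }
})

test_that("ES is scale-invariant and antisymmetric under list reversal", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:20)
  scores <- sort(abs(rnorm(20)), decreasing = TRUE)
  members <- sample(genes, 6)
  rl <- function(g, s) structure(data.frame(gene = g, score = s),
                                 absolute_mode = TRUE,
                                 class = c("ranked_list", "data.frame"))
  e1 <- enrichment_score(rl(genes, scores), members, p = 1)$es
  e2 <- enrichment_score(rl(genes, scores * 37.5), members, p = 1)$es
  expect_equal(e1, e2, tolerance = 1e-12)
  # equal weights (p = 0): reversing the list negates the ES
  f1 <- enrichment_score(rl(genes, scores), members, p = 0)$es
  f2 <- enrichment_score(rl(rev(genes), rev(scores)), members, p = 0)$es
  expect_equal(f1, -f2, tolerance = 1e-12)
})

test_that("fgsea computes the same weighted-KS statistic", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  for (rep in 1:20) {
    N <- 50
    genes <- sprintf("g%02d", 1:N)
    scores <- sort(abs(rnorm(N, sd = 1.5)), decreasing = TRUE)
    members <- sample(genes, 8)
    ranked <- structure(data.frame(gene = genes, score = scores),
                        absolute_mode = TRUE,
                        class = c("ranked_list", "data.frame"))
    got <- enrichment_score(ranked, members, p = 1)$es
    stats <- stats::setNames(scores, genes)
    want <- fgsea::calcGseaStat(stats, selectedStats = match(members, genes),
                                gseaParam = 1, scoreType = "std")
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("exhaustive 3v3 phenotype enumeration matches a brute-force null", {
  set.seed(31)
  n_genes <- 40
  genes <- sprintf("G%02d", 1:n_genes)
  X <- matrix(rnorm(n_genes * 6, mean = 7), n_genes, 6,
              dimnames = list(genes, sprintf("s%d", 1:6)))
  X[1:8, 1:3] <- X[1:8, 1:3] + 1.2
  em <- expr_matrix(X, "log2", rep(c("disease", "control"), each = 3))
  sets <- list(SIG = genes[1:8], NULL1 = genes[9:20], NULL2 = genes[21:32])
  cfg <- gsea_config(n_permutations = 1000, min_set_size = 5, seed = 9)
  expect_message(res <- gsea(em, sets, cfg), "exhaustive")
  expect_equal(attr(res, "n_permutations"), 19L)  # C(6,3) splits minus identity

  # oracle: recompute |s2n| ranking and ES for every label split by hand
  splits <- utils::combn(6, 3)
  obs_idx <- 1:3
  es_of <- function(didx, members) {
    s <- vapply(genes, function(g)
      abs(brute_s2n(X[g, didx], X[g, setdiff(1:6, didx)])), numeric(1))
    o <- order(-s, genes)
    brute_es(genes[o], s[o], members, p = 1)$es
  }
  for (nm in names(sets)) {
    es_obs <- es_of(obs_idx, sets[[nm]])
    perm_es <- apply(splits, 2, es_of, members = sets[[nm]])
    perm_es <- perm_es[apply(splits, 2, function(s) !setequal(s, obs_idx))]
    same <- if (es_obs >= 0) perm_es >= 0 else perm_es < 0
    p_oracle <- (1 + sum(abs(perm_es[same]) >= abs(es_obs))) / (1 + 19)
    expect_equal(res$nom_p[res$set == nm], p_oracle, tolerance = 1e-12)
  }
})

test_that("gsea results are reproducible under a fixed seed", {
  ps <- list(list(name = "PL", genes = sprintf("GENE%04d", 1:20),
                  delta_log2 = 1.5, direction = "up"))
  d <- synthetic_design(n_genes = 200, n_disease = 8, n_control = 8,
                        planted_sets = ps, n_decoy_sets = 8, seed = 4)
  co <- generate_cohort(d, "A")
  gm <- collapse_to_genes(co$log2, co$annotation)$matrix
  cfg <- gsea_config(n_permutations = 100, seed = 77)
  r1 <- gsea(gm, co$sets, cfg)
  r2 <- gsea(gm, co$sets, cfg)
  expect_identical(r1, r2)
  # leading-edge summaries live in [0, 1] as the report columns require
  expect_true(all(r1$tag_pct >= 0 & r1$tag_pct <= 1))
  expect_true(all(r1$gene_pct >= 0 & r1$gene_pct <= 1))
  expect_true(all(r1$signal >= 0 & r1$signal <= 1))
  expect_true(all(abs(r1$es) <= 1))
  # gene_set permutation mode runs and keeps the same observed ES
  cfg2 <- gsea_config(n_permutations = 100, seed = 77,
                      permutation_mode = "gene_set")
  r3 <- gsea(gm, co$sets, cfg2)
  expect_equal(sort(r3$es), sort(r1$es), tolerance = 1e-12)
})

test_that("significance filter is strict on p and inclusive on q", {
  res <- data.frame(set = paste0("S", 1:5),
                    nom_p = c(0.04, 0.05, 0.001, 0.2, 0.049),
                    fdr_q = c(0.25, 0.10, 0.26, 0.01, 0.249))
  cfg <- gsea_config()
  keep <- significant_sets(res, cfg)
  want <- res$set[res$nom_p < 0.05 & res$fdr_q <= 0.25]  # brute predicate
  expect_equal(keep$set, want)
  expect_equal(keep$set, c("S1", "S5"))
})
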