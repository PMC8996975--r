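#' Specify a synthetic two-class cohort design
#'
#' Describes one disease-vs-control cohort with optional planted gene sets.
#' The noise model is Normal on the log2 scale (i.e. log-normal intensity);
#' the linear track is derived from the log2 track as `2^x` times a
#' multiplicative noise term with unit median, so the two normalization
#' tracks measure the same underlying RNA.
#'
#' @param n_genes number of genes in the universe.
#' @param probes_per_gene probes representing each gene (>= 1).
#' @param n_disease,n_control samples per class.
#' @param planted_sets list of planted gene sets, each a list with elements
#'   `name`, `genes` (character), `delta_log2` (finite, non-zero effect in
#'   log2 units) and `direction` (`"up"` or `"down"`).
#' @param baseline_log2_mean,baseline_log2_sd baseline log2 intensity mean
#'   and per-probe noise SD.
#' @param linear_noise_sd log2-scale SD of the multiplicative noise applied
#'   when deriving the linear track (unit-median noise).
#' @param n_decoy_sets number of decoy gene sets drawn from non-planted
#'   genes, size-matched to the planted sets (or `decoy_set_size` when no
#'   sets are planted).
#' @param decoy_set_size decoy set size used when there are no planted sets.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_genes = 1000, probes_per_gene = 1,
                             n_disease = 20, n_control = 20,
                             planted_sets = list(),
                             baseline_log2_mean = 7, baseline_log2_sd = 1,
                             linear_noise_sd = 0.1,
                             n_decoy_sets = 20, decoy_set_size = 20,
                             seed = 1) {
  stopifnot(n_genes >= 1, n_disease >= 1, n_control >= 1,
            n_decoy_sets >= 0, decoy_set_size >= 1,
            baseline_log2_sd > 0, linear_noise_sd >= 0)
  if (probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  for (ps in planted_sets) {
    if (!all(c("name", "genes", "delta_log2", "direction") %in% names(ps)))
      stop("each planted set needs name, genes, delta_log2, direction")
    if (!is.finite(ps$delta_log2) || ps$delta_log2 == 0)
      stop("planted set '", ps$name,
           "': delta_log2 must be finite and non-zero (truth unidentifiable)")
    if (!ps$direction %in% c("up", "down"))
      stop("planted set '", ps$name, "': direction must be 'up' or 'down'")
    if (!all(ps$genes %in% genes))
      stop("planted set '", ps$name, "' references genes outside the universe")
  }
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 n_disease = as.integer(n_disease),
                 n_control = as.integer(n_control),
                 planted_sets = planted_sets,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 linear_noise_sd = linear_noise_sd,
                 n_decoy_sets = as.integer(n_decoy_sets),
                 decoy_set_size = as.integer(decoy_set_size),
                 genes = genes,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

# planted truth bookkeeping shared by the generators
planted_truth <- function(design) {
  up <- character(); down <- character()
  for (ps in design$planted_sets) {
    if (ps$direction == "up") up <- union(up, ps$genes)
    else down <- union(down, ps$genes)
  }
  list(enriched_sets = vapply(design$planted_sets, `[[`, character(1), "name"),
       up_genes = sort(up), down_genes = sort(down))
}

# decoy collection drawn from genes planted in none of the supplied designs
build_collection <- function(designs, seed) {
  d1 <- designs[[1]]
  sets <- list()
  planted_genes <- character()
  for (d in designs) for (ps in d$planted_sets) {
    sets[[ps$name]] <- unique(ps$genes)
    planted_genes <- union(planted_genes, ps$genes)
  }
  pool <- setdiff(d1$genes, planted_genes)
  sizes <- if (length(sets)) lengths(sets) else d1$decoy_set_size
  set.seed(derive_seed(seed, "decoys"))
  for (k in seq_len(d1$n_decoy_sets)) {
    sz <- min(sizes[[((k - 1L) %% length(sizes)) + 1L]], length(pool))
    sets[[sprintf("DECOY_SET_%03d", k)]] <- sample(pool, sz)
  }
  sets
}

#' Generate one synthetic cohort
#'
#' Draws the log2 track per probe from
#' `Normal(baseline + direction * delta_log2 * planted&diseased, sd)`, then
#' derives the linear track as `2^log2 * 2^Normal(0, linear_noise_sd)`
#' (unit-median multiplicative noise). Gene sets are the planted sets plus
#' size-matched decoys drawn from non-planted genes.
#'
#' @param design a [synthetic_design()].
#' @param cohort_id label used both in sample IDs and to split the seed so
#'   two cohorts generated from related designs get independent noise.
#' @param sets optional pre-built gene-set collection (used by
#'   [generate_two_cohorts()] so both cohorts share one collection).
#' @return list with elements `linear` and `log2` (both [expr_matrix()]
#'   with phenotype `disease`/`control`), `annotation` (data.frame
#'   `probe_id`, `gene_symbol`), `sets` (named list) and `truth`.
#' @export
generate_cohort <- function(design, cohort_id = "A", sets = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  probes <- as.vector(t(outer(d$genes, seq_len(d$probes_per_gene),
                              function(g, k) sprintf("%s_p%d", g, k))))
  probe_gene <- rep(d$genes, each = d$probes_per_gene)
  n <- d$n_disease + d$n_control
  samples <- sprintf("%s_S%02d", cohort_id, seq_len(n))
  phen <- factor(rep(c("disease", "control"), c(d$n_disease, d$n_control)),
                 levels = c("disease", "control"))

  set.seed(derive_seed(d$seed, paste0("cohort-", cohort_id)))
  mu <- matrix(d$baseline_log2_mean, nrow = length(probes), ncol = n,
               dimnames = list(probes, samples))
  # a gene planted in several sets is shifted once, and all its sets must
  # agree on the effect
  gene_shift <- stats::setNames(rep(0, d$n_genes), d$genes)
  for (ps in d$planted_sets) {
    shift <- if (ps$direction == "up") ps$delta_log2 else -ps$delta_log2
    prev <- gene_shift[ps$genes]
    if (any(prev != 0 & prev != shift))
      stop("gene(s) planted with conflicting effects across sets: ",
           paste(utils::head(ps$genes[prev != 0 & prev != shift], 3),
                 collapse = ", "))
    gene_shift[ps$genes] <- shift
  }
  mu[, phen == "disease"] <- mu[, phen == "disease"] +
    gene_shift[probe_gene]
  log2v <- mu + matrix(stats::rnorm(length(mu), sd = d$baseline_log2_sd),
                       nrow = nrow(mu))
  linv <- 2^log2v *
    2^matrix(stats::rnorm(length(mu), sd = d$linear_noise_sd), nrow = nrow(mu))
  dimnames(linv) <- dimnames(log2v) <- dimnames(mu)

  if (is.null(sets)) sets <- build_collection(list(d), d$seed)
  list(linear = expr_matrix(linv, "linear", phen),
       log2 = expr_matrix(log2v, "log2", phen),
       annotation = data.frame(probe_id = probes, gene_symbol = probe_gene,
                               stringsAsFactors = FALSE),
       sets = sets,
       truth = planted_truth(d))
}

#' Generate a pair of cohorts with a shared planted panel
#'
#' Both cohorts are generated over an identical gene universe and probe
#' annotation and one shared gene-set collection, with independent noise.
#' `shared_genes` must be planted in both designs with a consistent
#' direction; the joint truth lists them as the expected cross-cohort
#' intersection panel.
#'
#' @param design_a,design_b [synthetic_design()] objects with equal
#'   `n_genes` and `probes_per_gene`.
#' @param shared_genes gene symbols planted in both designs.
#' @return list with elements `a`, `b` (each as [generate_cohort()]) and
#'   `truth` (per-cohort truths plus `shared_panel`).
#' @export
generate_two_cohorts <- function(design_a, design_b, shared_genes = character()) {
  stopifnot(inherits(design_a, "synthetic_design"),
            inherits(design_b, "synthetic_design"))
  if (design_a$n_genes != design_b$n_genes ||
      design_a$probes_per_gene != design_b$probes_per_gene)
    stop("the two designs must share n_genes and probes_per_gene")
  dir_of <- function(design, g) {
    dirs <- unique(unlist(lapply(design$planted_sets,
                                 function(ps) if (g %in% ps$genes) ps$direction)))
    if (length(dirs) != 1L)
      stop("shared gene ", g, " must be planted exactly one way in each design")
    dirs
  }
  for (g in shared_genes) {
    if (dir_of(design_a, g) != dir_of(design_b, g))
      stop("shared gene ", g, " has inconsistent direction across cohorts")
  }
  sets <- build_collection(list(design_a, design_b), design_a$seed)
  a <- generate_cohort(design_a, "A", sets = sets)
  b <- generate_cohort(design_b, "B", sets = sets)
  list(a = a, b = b,
       truth = list(a = a$truth, b = b$truth,
                    shared_panel = sort(shared_genes)))
}

#' Paired cohort designs with a planted shared gene panel
#'
#' Builds the benchmark condition used throughout the package's
#' pipeline-level checks: two disease-vs-control cohorts, each with several
#' planted up-regulated gene sets that all contain the same small shared
#' panel plus cohort-specific members, so the shared genes recur across
#' many enriched pathways (the situation the leading-edge frequency score
#' exploits) while cohort-specific genes do not cross cohorts.
#'
#' @param seed integer seed driving set membership and, offset per cohort,
#'   the expression noise.
#' @param n_shared shared panel size (default 7).
#' @param n_genes gene universe size.
#' @param probes_per_gene probes per gene.
#' @param n_per_class samples per class in each cohort.
#' @param delta_log2 planted effect size (log2 units).
#' @param sets_per_cohort planted sets per cohort; each holds the shared
#'   panel plus `set_size - n_shared` genes drawn from that cohort's
#'   specific pool.
#' @param set_size planted set size.
#' @param pool_size cohort-specific gene pool size.
#' @param n_decoy_sets decoy sets in the shared collection.
#' @return list `a`, `b` ([synthetic_design()]s) and `shared` (gene symbols),
#'   ready for [generate_two_cohorts()].
#' @export
shared_panel_design <- function(seed, n_shared = 7, n_genes = 600,
                                probes_per_gene = 3, n_per_class = 20,
                                delta_log2 = 2, sets_per_cohort = 5,
                                set_size = 20, pool_size = 20,
                                n_decoy_sets = 20) {
  stopifnot(set_size > n_shared, pool_size >= set_size - n_shared,
            n_genes >= n_shared + 2 * pool_size)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  shared <- genes[seq_len(n_shared)]
  pool_a <- genes[n_shared + seq_len(pool_size)]
  pool_b <- genes[n_shared + pool_size + seq_len(pool_size)]
  set.seed(derive_seed(seed, "panel-design"))
  mk_sets <- function(label, pool) lapply(seq_len(sets_per_cohort), function(i)
    list(name = sprintf("PLANTED_%s_%02d", label, i),
         genes = c(shared, sample(pool, set_size - n_shared)),
         delta_log2 = delta_log2, direction = "up"))
  list(a = synthetic_design(n_genes = n_genes,
                            probes_per_gene = probes_per_gene,
                            n_disease = n_per_class, n_control = n_per_class,
                            planted_sets = mk_sets("A", pool_a),
                            n_decoy_sets = n_decoy_sets, seed = seed),
       b = synthetic_design(n_genes = n_genes,
                            probes_per_gene = probes_per_gene,
                            n_disease = n_per_class, n_control = n_per_class,
                            planted_sets = mk_sets("B", pool_b),
                            n_decoy_sets = n_decoy_sets,
                            seed = seed + 500000L),
       shared = shared)
}

#' Generate a synthetic qPCR Ct table
#'
#' Triplicate Ct values for one target gene and the reference gene per
#' sample, such that the expected DeltaDeltaCt of each non-calibrator group
#' relative to the first group equals `-planted_log2_shift` (one PCR cycle
#' is one log2 unit of expression).
#'
#' @param groups group labels; the first is the calibrator.
#' @param n_per_group samples per group (>= 3).
#' @param planted_log2_shift log2 expression shift of each non-calibrator
#'   group vs the calibrator (recycled across groups).
#' @param seed integer seed.
#' @param gene,ref_gene symbol labels for the target and reference assays.
#' @param sd_ct per-well technical noise SD in cycles.
#' @return long-format data.frame: `sample`, `group`, `gene`, `replicate`,
#'   `ct_gene`, `ct_ref`.
#' @export
generate_qpcr_fixture <- function(groups = c("AC", "AS", "LC"), n_per_group = 4,
                                  planted_log2_shift = 0, seed = 1,
                                  gene = "GENE1", ref_gene = "RNA18S",
                                  sd_ct = 0.15) {
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  stopifnot(length(groups) >= 2, sd_ct >= 0)
  shift <- c(0, rep_len(planted_log2_shift, length(groups) - 1L))
  set.seed(derive_seed(seed, "qpcr"))
  out <- list()
  for (gi in seq_along(groups)) {
    for (s in seq_len(n_per_group)) {
      sample_id <- sprintf("%s_%02d", groups[gi], s)
      ct_ref_true <- stats::rnorm(1, mean = 15, sd = 0.3)
      # higher expression = fewer cycles: shift lowers the target Ct
      ct_gene_true <- ct_ref_true + 10 - shift[gi]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample_id, group = groups[gi], gene = gene,
        replicate = 1:3,
        ct_gene = ct_gene_true + stats::rnorm(3, sd = sd_ct),
        ct_ref = ct_ref_true + stats::rnorm(3, sd = sd_ct),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic right-censored survival table
#'
#' Exponential event times with the hazard multiplied by `hazard_ratio`
#' for subjects whose expression lies above the population median of the
#' expression distribution. Censoring is independent exponential, with its
#' rate chosen so the expected censored fraction is about `censor_rate`.
#'
#' @param n subjects (>= 20).
#' @param hazard_ratio hazard multiplier for the high-expression group (> 0).
#' @param censor_rate expected fraction censored, in [0, 1).
#' @param seed integer seed.
#' @param separation distance between the two expression modes; 0 gives a
#'   unimodal Normal marker, large values a clean bimodal marker whose
#'   modes coincide with the hazard groups.
#' @param base_hazard baseline event hazard per month.
#' @return data.frame: `subject`, `time` (months), `event` (1 = death,
#'   0 = censored), `expression_value`.
#' @export
generate_survival_fixture <- function(n = 500, hazard_ratio = 1,
                                      censor_rate = 0.1, seed = 1,
                                      separation = 0, base_hazard = 0.02) {
  if (n < 20) stop("n must be >= 20")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  set.seed(derive_seed(seed, "survival"))
  comp <- sample(rep(0:1, length.out = n))   # balanced mixture halves
  expr <- stats::rnorm(n, mean = comp * separation, sd = 1)
  pop_median <- separation / 2   # median of the generative mixture
  high <- expr > pop_median
  haz <- base_hazard * ifelse(high, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = haz)
  if (censor_rate > 0) {
    # competing exponential censoring: P(censor) = rc / (rc + hazard)
    rc <- mean(haz) * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, rate = rc)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(subject = sprintf("S%04d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             expression_value = expr,
             stringsAsFactors = FALSE)
}
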