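#' GSEA configuration
#'
#' @param weight_exponent weighting exponent p applied to |score| in the
#'   running-sum hit increments (0 = classic unweighted KS, default 1).
#' @param n_permutations permutations for the null (default 1000).
#' @param permutation_mode `"phenotype"` (label shuffling; default) or
#'   `"gene_set"` (random member sets on the observed ranking, for tiny
#'   cohorts).
#' @param min_set_size,max_set_size set-size window after intersection with
#'   the ranked universe (defaults 15-500).
#' @param alpha_nom nominal-p threshold for [significant_sets()] (strict <).
#' @param fdr_cut FDR-q threshold for [significant_sets()] (inclusive <=).
#' @param seed integer seed for the permutation stream.
#' @param absolute rank genes by |metric| so up- and down-regulated members
#'   both enrich at the list top (absolute GSEA; default `TRUE`).
#' @param metric ranking metric: `"s2n"` (signal-to-noise with the
#'   classical variance floor; default), `"t"` (Welch-type t with the same
#'   floor) or `"diff"` (difference of class means).
#' @param allow_exhaustive when the requested permutations exceed the
#'   number of distinct label splits, enumerate all splits instead of
#'   sampling (default `TRUE`).
#' @return a `gsea_config` list.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 1000,
                        permutation_mode = c("phenotype", "gene_set"),
                        min_set_size = 15, max_set_size = 500,
                        alpha_nom = 0.05, fdr_cut = 0.25, seed = 1,
                        absolute = TRUE, metric = c("s2n", "t", "diff"),
                        allow_exhaustive = TRUE) {
  permutation_mode <- match.arg(permutation_mode)
  metric <- match.arg(metric)
  stopifnot(weight_exponent >= 0, n_permutations >= 1,
            min_set_size >= 1, min_set_size <= max_set_size)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 permutation_mode = permutation_mode,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 alpha_nom = alpha_nom, fdr_cut = fdr_cut,
                 seed = as.integer(seed), absolute = isTRUE(absolute),
                 metric = metric,
                 allow_exhaustive = isTRUE(allow_exhaustive)),
            class = "gsea_config")
}

# class-membership score matrix: X genes x samples, D samples x P indicator
# columns (1 = disease). Returns genes x P metric values (signed).
score_matrix <- function(X, D, metric = "s2n") {
  n <- nrow(D)
  nd <- colSums(D)
  nc <- n - nd
  if (any(nd < 2) || any(nc < 2))
    stop("each phenotype class needs >= 2 samples for ranking")
  tot1 <- rowSums(X); tot2 <- rowSums(X * X)
  M1d <- X %*% D
  M2d <- (X * X) %*% D
  mu_d <- sweep(M1d, 2, nd, "/")
  mu_c <- sweep(tot1 - M1d, 2, nc, "/")
  v_d <- sweep(sweep(M2d, 2, nd, "/") - mu_d^2, 2, nd / (nd - 1), "*")
  v_c <- sweep(sweep(tot2 - M2d, 2, nc, "/") - mu_c^2, 2, nc / (nc - 1), "*")
  v_d[v_d < 0] <- 0; v_c[v_c < 0] <- 0   # numerical guard
  if (metric == "diff") return(mu_d - mu_c)
  # classical variance floor: sd >= 0.2|mu| per class, 0.2 when mu = 0
  floor_of <- function(mu) ifelse(mu == 0, 0.2, 0.2 * abs(mu))
  sd_d <- pmax(sqrt(v_d), floor_of(mu_d))
  sd_c <- pmax(sqrt(v_c), floor_of(mu_c))
  if (metric == "s2n") (mu_d - mu_c) / (sd_d + sd_c)
  else (mu_d - mu_c) / sqrt(sd_d^2 / rep(nd, each = nrow(X)) +
                              sd_c^2 / rep(nc, each = nrow(X)))
}

#' Rank genes by a two-class differential-expression metric
#'
#' Scores each gene by the chosen metric between the two phenotype classes
#' (first factor level minus second; the generator and CLS readers put the
#' disease class first). In absolute mode the genes are ordered by |score|
#' descending and the stored score is |score|, so both up- and
#' down-regulated genes rank at the top. Ties break by gene symbol.
#'
#' @param x gene-level log2 [expr_matrix()].
#' @param absolute rank by absolute metric value (default `TRUE`).
#' @param metric `"s2n"`, `"t"` or `"diff"` (see [gsea_config()]).
#' @return a `ranked_list`: data.frame with columns `gene`, `score`
#'   (non-increasing) and attribute `absolute_mode`.
#' @export
rank_genes <- function(x, absolute = TRUE, metric = "s2n") {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- table(x$phenotype)
  if (any(tab < 2)) stop("each phenotype class needs >= 2 samples")
  D <- matrix(as.numeric(x$phenotype == levels(x$phenotype)[1]), ncol = 1)
  s <- score_matrix(x$values, D, metric)[, 1]
  if (absolute) s <- abs(s)
  ord <- order(-s, rownames(x$values), method = "radix")
  structure(data.frame(gene = rownames(x$values)[ord], score = s[ord],
                       stringsAsFactors = FALSE),
            absolute_mode = absolute, class = c("ranked_list", "data.frame"))
}

# Fast ES from sorted member positions. pos: 1-based hit ranks (ascending),
# w: |score|^p at those hits (same order), N: universe size. The running
# sum always ends at 0; its maxima sit at hit positions and its minima just
# before hits (or at the end), so only 2k + 1 candidates need checking.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  miss <- 1 / (N - k)
  NR <- sum(w)
  if (NR <= 0) w <- rep(1, k) else w <- w
  cw <- cumsum(w) / sum(w)
  drop_ <- (pos - seq_len(k)) * miss
  after <- cw - drop_
  before <- c(0, cw[-k]) - drop_
  mx <- max(after)
  mn <- min(before, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^p / N_R` at member (hit)
#' positions and `-1/(N - n_S)` elsewhere; the ES is the running-sum value
#' of maximal absolute magnitude (a tie between the positive and negative
#' extremum resolves to the positive one). For ES > 0 the leading edge is
#' the members at or before the peak; for ES < 0, at or after it.
#'
#' @param ranked a [rank_genes()] result.
#' @param members character vector of gene-set member symbols.
#' @param p weighting exponent (0 = classic KS).
#' @return list: `es`, `running_sum` (length N), `peak_rank` (1-based),
#'   `leading_edge` (character), `size` (members in the ranked universe).
#' @export
enrichment_score <- function(ranked, members, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"), p >= 0)
  hit <- ranked$gene %in% members
  n_s <- sum(hit)
  N <- nrow(ranked)
  if (n_s == 0L || n_s == N)
    stop("gene set has ", n_s, " of ", N,
         " ranked genes; miss denominator degenerate")
  w <- abs(ranked$score)^p
  w[!hit] <- 0
  NR <- sum(w[hit])
  if (NR <= 0) w[hit] <- 1 / n_s else w <- w / NR
  incr <- ifelse(hit, w, -1 / (N - n_s))
  run <- cumsum(incr)
  i_max <- which.max(run); i_min <- which.min(run)
  if (run[i_max] >= abs(run[i_min])) { es <- run[i_max]; peak <- i_max }
  else { es <- run[i_min]; peak <- i_min }
  le <- if (es > 0) ranked$gene[seq_len(peak)][hit[seq_len(peak)]]
  else if (es < 0) ranked$gene[peak:N][hit[peak:N]]
  else character(0)
  list(es = es, running_sum = run, peak_rank = peak,
       leading_edge = le, size = n_s)
}

#' Leading-edge summary statistics
#'
#' `tag%` is the fraction of the set in the leading edge; `gene%` the
#' fraction of the ranked list at or before the peak (after, mirrored, for
#' negative ES); `signal` combines both, rescaled for set size.
#'
#' @param es_result an [enrichment_score()] result (or any list with
#'   `es`, `peak_rank`, `leading_edge`, `size`).
#' @param N ranked-universe size.
#' @return list `tag_pct`, `gene_pct`, `signal`, all in `[0, 1]`.
#' @export
leading_edge_stats <- function(es_result, N) {
  size <- es_result$size
  n_le <- length(es_result$leading_edge)
  if (n_le == 0L)
    return(list(tag_pct = 0, gene_pct = 0, signal = 0))
  tag <- n_le / size
  gene <- if (es_result$es >= 0) es_result$peak_rank / N
  else (N - es_result$peak_rank + 1) / N
  list(tag_pct = tag, gene_pct = gene,
       signal = tag * (1 - gene) * N / (N - size))
}

# indicator matrix of permuted phenotype labelings (samples x P);
# exhaustive enumeration drops the identity labeling
permutation_design <- function(phenotype, cfg) {
  n <- length(phenotype)
  obs <- as.numeric(phenotype == levels(phenotype)[1])
  nd <- sum(obs)
  total <- choose(n, nd)
  exhaustive <- cfg$allow_exhaustive && is.finite(total) &&
    total - 1 <= cfg$n_permutations
  if (exhaustive) {
    cmb <- utils::combn(n, nd)
    D <- matrix(0, n, ncol(cmb))
    D[cbind(as.vector(cmb),
            rep(seq_len(ncol(cmb)), each = nd))] <- 1
    D <- D[, colSums(D == obs) < n, drop = FALSE]
    message("exhaustive phenotype enumeration: ", ncol(D),
            " distinct non-identity label splits (requested ",
            cfg$n_permutations, ")")
  } else {
    D <- vapply(seq_len(cfg$n_permutations),
                function(j) obs[sample.int(n)], numeric(n))
  }
  D
}

#' Permutation-based enrichment statistics for a gene-set collection
#'
#' For every gene set in the size window, computes the observed ES and a
#' permutation null (phenotype-label shuffling by default, falling back to
#' exhaustive enumeration when fewer distinct splits exist than requested
#' permutations; or random same-size member sets in `gene_set` mode), then
#' derives NES, nominal p (+1-smoothed, same-sign comparison), FDR q
#' (pooled-permutation procedure with cumulative-minimum coherence), FWER p
#' (permutation max-statistic) and the leading-edge statistics.
#'
#' @param x gene-level log2 [expr_matrix()].
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param cfg a [gsea_config()].
#' @return data.frame sorted by nominal p with columns `set`, `size`, `es`,
#'   `nes`, `nom_p`, `fdr_q`, `fwer_p`, `tag_pct`, `gene_pct`, `signal`,
#'   `peak_rank` and list-column `leading_edge`; attribute `skipped` names
#'   sets outside the size window, `n_permutations` the null size used.
#' @export
gsea <- function(x, collection, cfg = gsea_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(cfg, "gsea_config"))
  genes <- rownames(x$values)
  N <- length(genes)
  members <- lapply(collection, function(g) intersect(unique(g), genes))
  sizes <- lengths(members)
  ok <- sizes >= cfg$min_set_size & sizes <= cfg$max_set_size & sizes < N
  skipped <- data.frame(set = names(collection)[!ok], size = sizes[!ok],
                        stringsAsFactors = FALSE)
  members <- members[ok]
  if (!length(members)) stop("no gene set falls inside the size window")
  S <- length(members)
  idx <- lapply(members, match, genes)

  ranked <- rank_genes(x, absolute = cfg$absolute, metric = cfg$metric)
  obs <- lapply(members, function(m)
    enrichment_score(ranked, m, p = cfg$weight_exponent))
  # observed ES for the null comparisons goes through the same candidate
  # arithmetic as the permuted ES, so exact ties (e.g. the complementary
  # label split in absolute mode) compare as equal
  rpos <- stats::setNames(seq_len(N), ranked$gene)
  es_obs <- vapply(members, function(m) {
    ps <- sort(unname(rpos[m]))
    es_from_positions(ps, abs(ranked$score[ps])^cfg$weight_exponent, N)
  }, numeric(1))

  set.seed(derive_seed(cfg$seed, "gsea-perm"))
  if (cfg$permutation_mode == "phenotype") {
    D <- permutation_design(x$phenotype, cfg)
    P <- ncol(D)
    scores <- score_matrix(x$values, D, cfg$metric)
    if (cfg$absolute) scores <- abs(scores)
    es_perm <- matrix(NA_real_, S, P)
    for (j in seq_len(P)) {
      s <- scores[, j]
      o <- order(-s)
      inv <- integer(N); inv[o] <- seq_len(N)
      for (si in seq_len(S)) {
        ps <- inv[idx[[si]]]
        op <- order(ps)
        es_perm[si, j] <- es_from_positions(
          ps[op], abs(s[idx[[si]]][op])^cfg$weight_exponent, N)
      }
    }
  } else {
    P <- cfg$n_permutations
    sabs <- abs(ranked$score)^cfg$weight_exponent
    es_perm <- matrix(NA_real_, S, P)
    for (si in seq_len(S)) {
      k <- length(idx[[si]])
      for (j in seq_len(P)) {
        ps <- sort(sample.int(N, k))
        es_perm[si, j] <- es_from_positions(ps, sabs[ps], N)
      }
    }
  }

  # same-sign normalization per set (zero permutation ES counts positive)
  mean_pos <- apply(es_perm, 1L, function(v) mean(v[v >= 0]))
  mean_neg <- apply(es_perm, 1L, function(v) mean(abs(v[v < 0])))
  nes_obs <- ifelse(es_obs >= 0, es_obs / mean_pos, es_obs / mean_neg)
  nes_perm <- ifelse(es_perm >= 0, es_perm / mean_pos,
                     es_perm / mean_neg)

  # ties between permuted and observed ES count as exceedances; the 1e-9
  # slack keeps exact ties (e.g. complementary splits) from being broken
  # by floating-point summation order
  nom_p <- vapply(seq_len(S), function(si) {
    same <- if (es_obs[si] >= 0) es_perm[si, ] >= 0 else es_perm[si, ] < 0
    (1 + sum(abs(es_perm[si, same]) >= abs(es_obs[si]) - 1e-9)) / (1 + P)
  }, numeric(1))

  pooled_pos <- nes_perm[is.finite(nes_perm) & nes_perm >= 0]
  pooled_neg <- nes_perm[is.finite(nes_perm) & nes_perm < 0]
  obs_pos <- nes_obs[is.finite(nes_obs) & nes_obs >= 0]
  obs_neg <- nes_obs[is.finite(nes_obs) & nes_obs < 0]
  fdr_q <- vapply(seq_len(S), function(si) {
    nv <- nes_obs[si]
    if (!is.finite(nv)) return(NA_real_)
    if (nv >= 0) {
      num <- if (length(pooled_pos)) mean(pooled_pos >= nv) else 0
      den <- mean(obs_pos >= nv)
    } else {
      num <- if (length(pooled_neg)) mean(pooled_neg <= nv) else 0
      den <- mean(obs_neg <= nv)
    }
    min(1, num / den)
  }, numeric(1))
  # coherence: a more extreme NES never gets a larger q
  for (side in c(1, -1)) {
    sel <- which(is.finite(nes_obs) & sign(nes_obs) * side >= 0 &
                   (side > 0 | nes_obs < 0))
    if (length(sel) > 1) {
      o <- sel[order(-side * nes_obs[sel])]   # most extreme first
      fdr_q[o] <- rev(cummin(rev(fdr_q[o])))
    }
  }

  max_pos <- apply(nes_perm, 2L, function(v) {
    v <- v[is.finite(v) & v >= 0]; if (length(v)) max(v) else -Inf })
  min_neg <- apply(nes_perm, 2L, function(v) {
    v <- v[is.finite(v) & v < 0]; if (length(v)) min(v) else Inf })
  fwer_p <- ifelse(es_obs >= 0,
                   colMeansSafe(max_pos, nes_obs, `>=`),
                   colMeansSafe(min_neg, nes_obs, `<=`))

  le <- lapply(obs, function(o) leading_edge_stats(o, N))
  res <- data.frame(set = names(members),
                    size = lengths(members),
                    es = es_obs, nes = nes_obs, nom_p = nom_p,
                    fdr_q = fdr_q, fwer_p = fwer_p,
                    tag_pct = vapply(le, `[[`, numeric(1), "tag_pct"),
                    gene_pct = vapply(le, `[[`, numeric(1), "gene_pct"),
                    signal = vapply(le, `[[`, numeric(1), "signal"),
                    peak_rank = vapply(obs, `[[`, numeric(1), "peak_rank"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$leading_edge <- I(lapply(obs, `[[`, "leading_edge"))
  res <- res[order(res$nom_p, -abs(res$nes), res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "n_permutations") <- P
  attr(res, "permutation_mode") <- cfg$permutation_mode
  res
}

# fraction of per-permutation extrema at least as extreme as each observed
# NES; vectorized over observed values
colMeansSafe <- function(extrema, nes_obs, cmp) {
  vapply(nes_obs, function(nv) {
    if (!is.finite(nv)) return(NA_real_)
    mean(cmp(extrema, nv))
  }, numeric(1))
}

#' Filter enrichment results to the significant sets
#'
#' Keeps results with nominal p strictly below `alpha_nom` and FDR q at or
#' below `fdr_cut`, preserving the nominal-p ordering.
#'
#' @param results a [gsea()] result.
#' @param cfg a [gsea_config()] supplying the thresholds.
#' @return the qualifying subset of `results`.
#' @export
significant_sets <- function(results, cfg = gsea_config()) {
  keep <- !is.na(results$nom_p) & results$nom_p < cfg$alpha_nom &
    !is.na(results$fdr_q) & results$fdr_q <= cfg$fdr_cut
  res <- results[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an enrichment report TSV
#'
#' Columns match the conventional GSEA report: `set`, `size`, `ES`, `NES`,
#' `NOM p-value`, `FDR q-value`, `FWER p-value`, `tag %`, `gene %`,
#' `signal`, `leading_edge` (semicolon-joined).
#'
#' @param results a [gsea()] result.
#' @param path output file.
#' @export
write_enrichment_report <- function(results, path) {
  out <- data.frame(
    set = results$set, size = results$size, ES = results$es,
    NES = results$nes, `NOM p-value` = results$nom_p,
    `FDR q-value` = results$fdr_q, `FWER p-value` = results$fwer_p,
    `tag %` = results$tag_pct, `gene %` = results$gene_pct,
    signal = results$signal,
    leading_edge = vapply(results$leading_edge, paste, character(1),
                          collapse = ";"),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
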