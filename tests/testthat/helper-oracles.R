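# Independent brute-force oracles used across the suite. These are written
# as plain loops over definitions, deliberately sharing no code with the
# package internals.

# weighted-KS enrichment score by explicit position-by-position walk
brute_es <- function(genes, scores, members, p) {
  N <- length(genes)
  hit <- genes %in% members
  k <- sum(hit)
  stopifnot(k > 0, k < N)
  w <- abs(scores)^p
  nr <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) cur <- cur + (if (nr > 0) w[i] / nr else 1 / k)
    else cur <- cur - 1 / (N - k)
    run[i] <- cur
  }
  mx <- max(run); mn <- min(run)
  list(es = if (mx >= abs(mn)) mx else mn, run = run)
}

# signal-to-noise with the classical variance floor, one gene at a time
brute_s2n <- function(xd, xc) {
  fl <- function(m) if (m == 0) 0.2 else 0.2 * abs(m)
  sd_d <- max(sd(xd), fl(mean(xd)))
  sd_c <- max(sd(xc), fl(mean(xc)))
  (mean(xd) - mean(xc)) / (sd_d + sd_c)
}

# the two filter predicates evaluated probe by probe
brute_filter <- function(lin, lg2, floor_, cv_lo, cv_hi) {
  keep <- character(0)
  for (pr in rownames(lin)) {
    m <- mean(lin[pr, ])
    mu <- mean(lg2[pr, ])
    cv <- if (mu == 0) NA else 100 * sd(lg2[pr, ]) / mu
    if (m >= floor_ && !is.na(cv) && cv >= cv_lo && cv <= cv_hi)
      keep <- c(keep, pr)
  }
  keep
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
brute_mw <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u_obs <- u_of(a, b)
  us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# product-limit estimate walked over distinct times by hand
brute_km <- function(time, event) {
  o <- order(time, -event)   # events precede censorings at tied times
  time <- time[o]; event <- event[o]
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# log-rank chi-square from the hypergeometric sums at each event time
brute_logrank_chi2 <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (tt in ts) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & grp == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# small labelled matrix constructor for toys
toy_expr <- function(values, scale, phenotype,
                     rows = sprintf("p%02d", seq_len(nrow(values)))) {
  dimnames(values) <- list(rows, sprintf("s%02d", seq_len(ncol(values))))
  expr_matrix(values, scale, phenotype)
}

# pipeline-level tests use the package's benchmark condition (several
# planted sets per cohort around a 7-gene shared panel); thin wrapper so
# tests can scale it down
shared_two_cohort_design <- function(seed, n_genes = 600, probes = 3,
                                     n_per_class = 20, delta = 2,
                                     n_decoys = 20) {
  shared_panel_design(seed, n_genes = n_genes, probes_per_gene = probes,
                      n_per_class = n_per_class, delta_log2 = delta,
                      n_decoy_sets = n_decoys)
}
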