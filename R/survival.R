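#' Split subjects by marker expression
#'
#' Median rule: `high` is expression strictly above the sample median,
#' `low` at or below it (median-tied values go low). The cutoff rule uses
#' a supplied threshold the same way. Best-cutoff scanning is deliberately
#' not offered: optimizing the split inflates the log-rank test.
#'
#' @param records data.frame with columns `time`, `event`,
#'   `expression_value` (as from [generate_survival_fixture()]).
#' @param rule `"median"` or `"cutoff"`.
#' @param cutoff threshold for the cutoff rule.
#' @return list `high`, `low` (row subsets), `threshold`.
#' @export
split_by_expression <- function(records, rule = c("median", "cutoff"),
                                cutoff = NULL) {
  rule <- match.arg(rule)
  v <- records$expression_value
  if (length(unique(v)) < 2) stop("all expression values identical; no split")
  thr <- if (rule == "median") stats::median(v) else {
    if (is.null(cutoff)) stop("cutoff rule needs a cutoff value")
    cutoff
  }
  list(high = records[v > thr, , drop = FALSE],
       low = records[v <= thr, , drop = FALSE],
       threshold = thr)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i); censored
#' subjects leave the risk set after their time, and events precede
#' censorings tied at the same time (the estimator's standard convention,
#' as computed by [survival::survfit()]).
#'
#' @param records data.frame with `time` and `event` columns.
#' @return a `km_curve`: data.frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` over the distinct observed times.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stop("empty group")
  if (any(records$time < 0)) stop("negative follow-up times")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Survival probability at a time point
#'
#' @param curve a [km_estimate()] result.
#' @param t time point.
#' @return S(t): the step-function value at `t` (1 before the first event).
#' @export
km_surv_at <- function(curve, t) {
  i <- findInterval(t, curve$time)
  if (i == 0) 1 else curve$surv[i]
}

#' Log-rank test and O/E hazard ratio
#'
#' Standard log-rank comparison of the high vs low group (hypergeometric
#' observed-vs-expected deaths at each distinct event time, via
#' [survival::survdiff()]); HR = (O_high/E_high) / (O_low/E_low) with
#' 95% CI `exp(log HR +/- 1.96 sqrt(1/E_high + 1/E_low))`. A group with
#' zero events yields an unbounded HR, flagged but with the test still
#' reported.
#'
#' @param high,low data.frames with `time` and `event` columns.
#' @return list `chi2`, `p` (1 df), `hr`, `ci95` (length 2), `obs`, `exp`
#'   (high/low), `unbounded` flag.
#' @export
logrank_hr <- function(high, low) {
  if (!nrow(high) || !nrow(low)) stop("both groups must be nonempty")
  dat <- rbind(data.frame(time = high$time, event = high$event, grp = "high"),
               data.frame(time = low$time, event = low$event, grp = "low"))
  if (sum(dat$event) < 1) stop("need at least one event overall")
  dat$grp <- factor(dat$grp, levels = c("high", "low"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  o <- as.numeric(sd_$obs); e <- as.numeric(sd_$exp)   # order: high, low
  chi2 <- as.numeric(sd_$chisq)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  unbounded <- o[1] == 0 || o[2] == 0
  hr <- if (unbounded) {
    if (o[1] == 0 && o[2] == 0) NA_real_
    else if (o[2] == 0) Inf else 0
  } else (o[1] / e[1]) / (o[2] / e[2])
  se <- sqrt(1 / e[1] + 1 / e[2])
  ci <- if (unbounded || is.na(hr)) c(NA_real_, NA_real_)
  else exp(log(hr) + c(-1.96, 1.96) * se)
  list(chi2 = chi2, p = p, hr = hr, ci95 = ci,
       obs = stats::setNames(o, c("high", "low")),
       exp = stats::setNames(e, c("high", "low")),
       unbounded = unbounded)
}
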