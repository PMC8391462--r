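# Downstream statistics: per-cohort Pearson co-expression with a t-based
# significance test and Fisher-z interval, two-sample Kolmogorov-Smirnov
# comparison of variant-score distributions against an all-missense null,
# and median-split Kaplan-Meier survival with chromosome-3 subgroups.

#' Pearson correlation with t-test and Fisher-z interval
#'
#' Sample Pearson r with `t = r * sqrt(n-2) / sqrt(1-r^2)`, a two-sided p
#' from the t distribution on `n - 2` df, a 95% Fisher-z confidence
#' interval, and the weak-correlation flag (`-0.5 < r < 0.5`) used to call
#' a tumor-disturbed co-expression pattern.
#'
#' @param x,y numeric vectors of equal length `>= 3`, non-zero variance.
#' @return one-row data.frame: `n`, `r`, `t`, `p`, `ci_lo`, `ci_hi`,
#'   `weak_flag`.
#' @export
pearson_with_test <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3, all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance input")
  }
  r <- cor(x, y)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  data.frame(n = n, r = r, t = tstat, p = max(p, .Machine$double.xmin),
             ci_lo = ci[1], ci_hi = ci[2],
             weak_flag = r > -0.5 & r < 0.5)
}

#' Per-cancer-type, per-cohort co-expression table
#'
#' One correlation row per (cancer type, cohort) for the `PPARG`/`DNMT1`
#' columns; cohorts with fewer than 3 samples are skipped with a warning.
#' An optional Benjamini-Hochberg column is appended; raw p-values are
#' reported either way.
#'
#' @param expression data.frame with columns `cancer_type`, `cohort`
#'   (`tumor`/`control`), `PPARG`, `DNMT1`.
#' @param adjust add a `p_bh` column.
#' @return data.frame sorted by cancer_type then cohort.
#' @export
correlate_by_cancer <- function(expression, adjust = FALSE) {
  stopifnot(all(c("cancer_type", "cohort", "PPARG", "DNMT1") %in%
                  names(expression)))
  out <- list()
  for (ct in sort(unique(expression$cancer_type))) {
    for (co in c("control", "tumor")) {
      sub <- expression[expression$cancer_type == ct &
                          expression$cohort == co, , drop = FALSE]
      if (nrow(sub) < 3) {
        warning("skipping ", ct, "/", co, ": fewer than 3 samples")
        next
      }
      row <- pearson_with_test(log(sub$PPARG), log(sub$DNMT1))
      out[[length(out) + 1]] <- cbind(
        data.frame(cancer_type = ct, cohort = co, stringsAsFactors = FALSE),
        row)
    }
  }
  res <- do.call(rbind, out)
  if (isTRUE(adjust) && !is.null(res)) res$p_bh <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum absolute difference of the two empirical CDFs,
#' evaluated at every observed value; the two-sided p-value uses the
#' asymptotic Kolmogorov distribution at `sqrt(n_eff) * D` with effective
#' size `n_eff = n_obs * n_null / (n_obs + n_null)`. For small untied
#' samples an exact p is available behind `exact = TRUE` (delegated to
#' [stats::ks.test()]'s exact path).
#'
#' @param observed,null numeric vectors (non-empty).
#' @param exact use the exact small-sample p-value instead.
#' @return one-row data.frame: `D`, `p`, `n_obs`, `n_null`.
#' @export
ks_two_sample <- function(observed, null, exact = FALSE) {
  n1 <- length(observed); n2 <- length(null)
  if (!n1 || !n2) stop("both samples must be non-empty")
  pts <- sort(unique(c(observed, null)))
  F1 <- vapply(pts, function(v) mean(observed <= v), numeric(1))
  F2 <- vapply(pts, function(v) mean(null <= v), numeric(1))
  D <- max(abs(F1 - F2))
  n_eff <- n1 * n2 / (n1 + n2)
  if (exact) {
    p <- suppressWarnings(
      stats::ks.test(observed, null, exact = TRUE)$p.value)
  } else {
    p <- kolmogorov_sf(sqrt(n_eff) * D)
  }
  data.frame(D = D, p = min(max(p, .Machine$double.xmin), 1),
             n_obs = n1, n_null = n2)
}

# survival function of the Kolmogorov distribution:
# P(K > lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Split a cohort at an expression quantile (default: median)
#'
#' `high` = strictly above the cutpoint, `low` = at or below (ties go
#' low). Errors when either group would be empty (e.g. constant
#' expression).
#'
#' @param expression numeric vector, length `>= 4`.
#' @param quantile cutpoint quantile; 0.5 reproduces the usual
#'   high/low median split.
#' @return character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(expression, quantile = 0.5) {
  stopifnot(length(expression) >= 4)
  cut <- stats::quantile(expression, quantile, names = FALSE)
  grp <- ifelse(expression > cut, "high", "low")
  if (length(unique(grp)) < 2) {
    stop("degenerate split: all cases on one side of the cutpoint")
  }
  grp
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; censoring
#' decrements the risk set without dropping the curve. Computed with
#' [survival::survfit()] and returned as a plain table.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` at every distinct observed time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard hypergeometric observed-vs-expected log-rank (no continuity
#' correction), 1 df, via [survival::survdiff()].
#'
#' @param time,event follow-up and status vectors.
#' @param group two-level grouping vector.
#' @return one-row data.frame: `chisq`, `p`, `n1`, `n2`, `events`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2)
  if (sum(event) == 0) stop("log-rank undefined: no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  data.frame(chisq = sd$chisq,
             p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
             n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2]),
             events = sum(event))
}

#' Median-split survival inside a chromosome-3 subgroup
#'
#' Filters the cohort to the requested chromosome-3 class, median-splits
#' the filtered cases on expression, and compares the high vs low group by
#' Kaplan-Meier and log-rank.
#'
#' @param cohort data.frame with `time`, `event`, `expression`,
#'   `chr3_class` (as from [simulate_survival_cohort()]).
#' @param class_filter `"all"`, `"disomy3"` or `"monosomy3"`.
#' @param quantile expression cutpoint quantile.
#' @return list with `logrank`, `km` (named list of curves for `high` and
#'   `low`), `n` (per-group sizes) and `class_filter`.
#' @export
subgroup_survival <- function(cohort, class_filter = c("all", "disomy3",
                                                       "monosomy3"),
                              quantile = 0.5) {
  class_filter <- match.arg(class_filter)
  sub <- if (class_filter == "all") cohort
    else cohort[cohort$chr3_class == class_filter, , drop = FALSE]
  if (nrow(sub) < 4) {
    stop("subgroup '", class_filter, "' too small (", nrow(sub), " cases)")
  }
  grp <- median_split(sub$expression, quantile)
  list(
    logrank = logrank_test(sub$time, sub$event, grp),
    km = list(high = km_estimate(sub$time[grp == "high"],
                                 sub$event[grp == "high"]),
              low = km_estimate(sub$time[grp == "low"],
                                sub$event[grp == "low"])),
    n = table(grp), class_filter = class_filter)
}

#' Summarize a uveal-melanoma style clinical cohort
#'
#' Cohort partition by chromosome-3 class and, when an `sf3b1_mut` column
#' is present, the count of SF3B1-mutant cases in the high vs low
#' expression group (median split) among disomy 3 tumors.
#'
#' @param cohort clinical data.frame with `time`, `event`, `expression`,
#'   `chr3_class` and optionally `sf3b1_mut` (0/1).
#' @return named list of counts.
#' @export
summarize_uvm_cohort <- function(cohort) {
  out <- list(n_cases = nrow(cohort),
              n_disomy3 = sum(cohort$chr3_class == "disomy3"),
              n_monosomy3 = sum(cohort$chr3_class == "monosomy3"))
  if ("sf3b1_mut" %in% names(cohort)) {
    d3 <- cohort[cohort$chr3_class == "disomy3", , drop = FALSE]
    grp <- median_split(d3$expression)
    out$sf3b1_high_expr <- sum(d3$sf3b1_mut == 1 & grp == "high")
    out$sf3b1_low_expr <- sum(d3$sf3b1_mut == 1 & grp == "low")
  }
  out
}
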