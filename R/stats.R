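#' @title Statistical tests used by the imaging analyses
#' @description The four procedures invoked by the figure-level analyses —
#'   two-tailed two-sample t test, one-way ANOVA, two-sample
#'   Kolmogorov-Smirnov test, and the log-rank test — implemented directly
#'   from their defining formulas so that every reported statistic is
#'   auditable. Each returns a `test_result`.
#' @name ivmotion-stats
NULL

.test_result <- function(name, statistic, p_value, df = NULL, note = NULL) {
  structure(list(test = name, statistic = statistic,
                 p_value = min(max(p_value, 0), 1), df = df, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g", x$test, x$statistic, x$p_value))
  if (!is.null(x$df)) cat(", df =", paste(x$df, collapse = ", "))
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Two-tailed two-sample t test (pooled variance)
#'
#' Student's t with the pooled variance estimate and
#' `df = n_a + n_b - 2`; the p value is two-sided. Degenerate inputs with
#' zero pooled variance return `p = 1` when the means agree and `p = 0`
#' (flagged) when they differ.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return a `test_result`.
#' @export
t_test_two_tailed <- function(a, b) {
  .assert(length(a) >= 2 && length(b) >= 2, "each group needs n >= 2")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  df <- na + nb - 2
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  dm <- mean(a) - mean(b)
  if (se == 0) {
    if (dm == 0) return(.test_result("two-tailed t (pooled)", 0, 1, df,
                                     "zero variance, equal means"))
    return(.test_result("two-tailed t (pooled)", sign(dm) * Inf, 0, df,
                        "zero variance, unequal means"))
  }
  tstat <- dm / se
  .test_result("two-tailed t (pooled)", tstat, 2 * stats::pt(-abs(tstat), df), df)
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total
#'   `N > k`).
#' @return a `test_result`.
#' @export
anova_oneway <- function(groups) {
  .assert(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  .assert(N > k, "total n must exceed the number of groups")
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (gm - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    if (ss_between == 0)
      return(.test_result("one-way ANOVA", 0, 1, c(df1, df2),
                          "all observations identical"))
    return(.test_result("one-way ANOVA", Inf, 0, c(df1, df2),
                        "zero within-group variance"))
  }
  fstat <- (ss_between / df1) / (ss_within / df2)
  .test_result("one-way ANOVA", fstat,
               stats::pf(fstat, df1, df2, lower.tail = FALSE), c(df1, df2))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` over the pooled sample points
#' (right-continuous ECDFs). The p value evaluates the asymptotic
#' Kolmogorov distribution at the finite-sample-corrected argument
#' `(sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D` (Stephens' correction) with
#' effective size `ne = n_a n_b / (n_a + n_b)`; at moderate group sizes
#' this reproduces the rejection behaviour of the exact test, whereas the
#' uncorrected argument is noticeably conservative. A warning is issued
#' for groups below 10 observations, where any asymptotic p is crude.
#'
#' @param a,b numeric samples, each of length >= 1.
#' @return a `test_result`.
#' @export
ks_two_sample <- function(a, b) {
  .assert(length(a) >= 1 && length(b) >= 1, "each group needs n >= 1")
  if (length(a) < 10 || length(b) < 10)
    warning("asymptotic KS p value is inaccurate below n = 10 per group")
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  .test_result("two-sample Kolmogorov-Smirnov", D, .kolmogorov_sf(lambda))
}

# survival function of the Kolmogorov distribution, Q(t) = 2 sum (-1)^{j-1} exp(-2 j^2 t^2)
.kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  j <- seq_len(100)
  terms <- (-1)^(j - 1) * exp(-2 * j^2 * t^2)
  min(max(2 * sum(terms), 0), 1)
}

#' Log-rank test for two survival groups
#'
#' At each distinct event time the observed events in group 1 are compared
#' with the expectation under the hypergeometric model given the risk
#' sets; the statistic `(sum O - sum E)^2 / sum V` is referred to
#' chi-square with 1 degree of freedom. Subjects censored at an event time
#' are counted as at risk at that time; tied event times share one risk
#' table row.
#'
#' @param time survival times (> 0), or a data frame with columns
#'   `time`, `event`, `group` (as produced by [simulate_survival()]).
#' @param event event indicator (1 died, 0 censored).
#' @param group two-level group label.
#' @return a `test_result`.
#' @export
log_rank <- function(time, event = NULL, group = NULL) {
  if (is.data.frame(time)) {
    event <- time$event; group <- time$group; time <- time$time
  }
  .assert(all(time > 0), "survival times must be positive")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  group <- as.factor(group)
  .assert(nlevels(group) == 2, "log-rank here compares exactly two groups")
  .assert(all(table(group) > 0), "each group needs at least one subject")
  .assert(sum(event) >= 1, "no events: log-rank undefined")
  g1 <- levels(group)[1]
  event_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in event_times) {
    at_risk <- time >= tt
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_tot <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group == g1)
    O <- O + d1
    E <- E + n1 * d_tot / n_tot
    if (n_tot > 1)
      V <- V + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1)
  }
  if (V == 0)
    return(.test_result("log-rank", 0, 1, 1, "no between-group information"))
  chisq <- (O - E)^2 / V
  .test_result("log-rank", chisq, stats::pchisq(chisq, 1, lower.tail = FALSE), 1)
}

#' Mean, SD and SEM summary of grouped values
#'
#' Emits both spread conventions (mean +/- SD for the dot plots, mean +/-
#' SEM for the text), labelled explicitly.
#'
#' @param values numeric vector.
#' @param group group label vector of the same length.
#' @return data frame `group, n, mean, sd, sem`.
#' @export
group_summary <- function(values, group) {
  .assert(length(values) == length(group), "values and group lengths differ")
  out <- do.call(rbind, lapply(split(values, group), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
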