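# Survival stratification and elementary group statistics: Kaplan-Meier,
# log-rank, maximally selected cutpoint, Mann-Whitney U, IHC composite.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with right censoring, via [survival::survfit()].
#'
#' @param df data frame of one record per patient.
#' @param time,event column names (tidy-eval): positive follow-up times and
#'   0/1 event indicators.
#' @return tibble: time, n_risk, n_event, n_censor, survival (non-increasing,
#'   starting from 1 at time 0 implicitly).
#' @export
km_estimate <- function(df, time = time, event = event) {
  t <- dplyr::pull(df, {{ time }})
  e <- dplyr::pull(df, {{ event }})
  assert_that(length(t) >= 1, "need at least one record")
  assert_that(all(t > 0), "times must be positive")
  assert_that(all(e %in% c(0, 1)), "events must be 0/1")
  fit <- survival::survfit(survival::Surv(t, e) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard aggregated-risk-set log-rank chi-square with 1 degree of
#' freedom, two-sided p-value.
#'
#' @param df data frame of one record per patient.
#' @param time,event,group column names (tidy-eval); `group` must take
#'   exactly two values, each with at least one record.
#' @return One-row tibble: statistic, df, p_value.
#' @export
logrank_test <- function(df, time = time, event = event, group = group) {
  t <- dplyr::pull(df, {{ time }})
  e <- dplyr::pull(df, {{ event }})
  g <- as.factor(dplyr::pull(df, {{ group }}))
  assert_that(nlevels(droplevels(g)) == 2,
              "group must take exactly two values with records in each")
  assert_that(all(t > 0), "times must be positive")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  stat <- sd$chisq
  tibble::tibble(statistic = stat, df = 1,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Maximally selected survival cutpoint
#'
#' Scans every split of a continuous variable leaving at least `min_prop` of
#' the records on each side and returns the split maximizing the
#' standardized log-rank statistic. The reported p-value comes from the
#' subsequent log-rank test at the chosen split and is NOT corrected for the
#' selection, which inflates type-I error; a warning says so.
#'
#' @param df data frame of one record per patient.
#' @param var column name (tidy-eval) of the stratifying expression value.
#' @param time,event column names (tidy-eval).
#' @param min_prop minimum fraction of records per side (default 0.1).
#' @return list of class `cutpoint_fit`: `cutpoint`, `statistic` (max
#'   standardized log-rank |z|), `p_value`, `data` (input plus a
#'   `group` column "high"/"low"), `var` (name).
#' @export
optimal_cutpoint <- function(df, var, time = time, event = event,
                             min_prop = 0.1) {
  x <- dplyr::pull(df, {{ var }})
  t <- dplyr::pull(df, {{ time }})
  e <- dplyr::pull(df, {{ event }})
  n <- length(x)
  assert_that(n >= 10, "need at least 10 records")
  assert_that(sd(x) > 0, "expression is constant; no cutpoint exists")
  min_side <- max(1L, ceiling(min_prop * n))
  xs <- sort(unique(x))
  cands <- (xs[-1] + xs[-length(xs)]) / 2
  cands <- cands[vapply(cands, function(cc) {
    hi <- sum(x > cc)
    hi >= min_side && (n - hi) >= min_side
  }, logical(1))]
  if (length(cands) == 0) {
    abort("no valid split leaves min_prop of records on each side")
  }
  z <- vapply(cands, function(cc) {
    grp <- x > cc
    if (sum(e[grp]) + sum(e[!grp]) == 0) return(0)
    sqrt(survival::survdiff(survival::Surv(t, e) ~ grp)$chisq)
  }, numeric(1))
  best <- cands[which.max(z)]
  out <- tibble::as_tibble(df)
  out$group <- ifelse(x > best, "high", "low")
  warn(paste("cutpoint selection inflates the type-I error of the reported",
             "log-rank p-value; no selection correction is applied"))
  lr <- logrank_test(out, {{ time }}, {{ event }}, group)
  structure(list(cutpoint = best, statistic = max(z),
                 p_value = lr$p_value, data = out,
                 var = rlang::as_name(rlang::enquo(var))),
            class = "cutpoint_fit")
}

#' @export
print.cutpoint_fit <- function(x, ...) {
  cat("<cutpoint_fit> ", x$var, " > ", format(x$cutpoint),
      ": max |z| = ", format(x$statistic, digits = 4),
      ", log-rank p = ", format(x$p_value, digits = 4),
      " (uncorrected)\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value by enumeration of all group assignments when
#' `n_a + n_b <= 12`; otherwise the tie-corrected normal approximation
#' (no continuity correction).
#'
#' @param a,b numeric samples.
#' @return One-row tibble: u (U statistic of sample `a`), p_value, n_a,
#'   n_b, method.
#' @export
mann_whitney <- function(a, b) {
  assert_that(length(a) >= 1 && length(b) >= 1,
              "both samples must be non-empty")
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= 12) {
    subsets <- utils::combn(n, na)
    u_all <- colSums(matrix(r[subsets], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      p <- 2 * pnorm(-abs(u - mu) / sqrt(sigma2))
    }
    method <- "normal approximation (tie-corrected)"
  }
  tibble::tibble(u = u, p_value = min(1, p), n_a = na, n_b = nb,
                 method = method)
}

#' IHC composite score
#'
#' Product of staining intensity (0 = none, 1 = weak, 2 = moderate,
#' 3 = strong) and positive-area category (0 = 0%, 1 = 1-25%, 2 = 25-50%,
#' 3 = 50-75%, 4 = 75-100%), ranging 0-12.
#'
#' @param intensity integer(s) in 0..3.
#' @param area integer(s) in 0..4.
#' @return Integer composite score(s).
#' @export
ihc_composite <- function(intensity, area) {
  assert_that(all(intensity %in% 0:3), "intensity must be in 0..3")
  assert_that(all(area %in% 0:4), "area must be in 0..4")
  as.integer(intensity) * as.integer(area)
}

#' Compare IHC composite scores between two groups
#'
#' Convenience wrapper applying [mann_whitney()] to the composite scores of
#' the two groups in an IHC table.
#'
#' @param df tibble with columns `group` (two values) and `composite`.
#' @return One-row tibble from [mann_whitney()] plus the group labels.
#' @export
ihc_compare <- function(df) {
  groups <- sort(unique(df$group))
  assert_that(length(groups) == 2, "need exactly two groups")
  res <- mann_whitney(df$composite[df$group == groups[1]],
                      df$composite[df$group == groups[2]])
  res$group_a <- groups[1]
  res$group_b <- groups[2]
  res
}
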