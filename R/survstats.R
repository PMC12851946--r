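# Survival statistics toolkit: Kaplan-Meier with Greenwood CIs, two-group
# log-rank, Cox proportional hazards (via survival::coxph, Efron ties),
# Harrell's concordance, non-parametric group tests, bootstrap CIs.
# All p-values are two-sided.

#' Kaplan-Meier product-limit estimate
#'
#' @param time event/censoring times (> 0).
#' @param event 1 = event, 0 = censored.
#' @param conf_level confidence level for the Greenwood band (default 0.95).
#' @return object of class `km_curve`: data.frame(time, n_risk, n_event,
#'   n_censor, surv, se, lower, upper). S(0) = 1 is implicit; the band uses
#'   the log-transformed Greenwood variance, clipped to \[0,1\], so it always
#'   contains the estimate.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  abort_if(any(time <= 0), "survival times must be > 0")
  abort_if(!all(event %in% c(0, 1)), "event must be 0/1")
  if (all(event == 0) && length(unique(time)) == 1) {
    warning("all observations censored at the same time: flat curve")
  }
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood on the log scale
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  z <- qnorm(1 - (1 - conf_level) / 2)
  loghaz_se <- sqrt(gw)
  lower <- clamp(exp(log(pmax(surv, 1e-12)) - z * loghaz_se), 0, 1)
  upper <- clamp(exp(log(pmax(surv, 1e-12)) + z * loghaz_se), 0, 1)
  lower[surv == 0] <- 0; upper[surv == 0] <- 0
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv, se = se,
                       lower = lower, upper = upper),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a `km_curve` at arbitrary times
#' @param curve a [km_estimate()] result.
#' @param at times at which to read off S(t).
#' @return numeric survival probabilities (S = 1 before the first event time).
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard O-E/V chi-square with 1 df over the pooled event times,
#' two-sided p.
#'
#' @param time,event pooled survival data.
#' @param group two-level grouping vector.
#' @return list(statistic, p_value, observed, expected, groups).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  abort_if(nlevels(g) != 2, "logrank_test requires exactly two groups")
  abort_if(any(table(g) == 0), "both groups must be non-empty")
  if (sum(event) == 0) {
    warning("no events: log-rank undefined")
    return(list(statistic = NA_real_, p_value = NA_real_,
                observed = c(0, 0), expected = c(0, 0),
                groups = levels(g)))
  }
  dt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + n1 * d / n
    if (n > 1) v <- v + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(statistic = stat, p_value = p,
       observed = c(o1, sum(event) - o1),
       expected = c(e1, sum(event) - e1),
       groups = levels(g))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood Newton fit with Efron tie handling (backed by
#' `survival::coxph`); hazard ratios with Wald confidence intervals.
#' Non-convergence or separation is flagged, never silently returned.
#'
#' @param time,event survival data.
#' @param covariates numeric vector, matrix or data.frame.
#' @param conf_level Wald CI level.
#' @return data.frame(term, beta, se, hr, hr_lower, hr_upper, p_value) with
#'   attribute `converged`.
#' @export
cox_fit <- function(time, event, covariates, conf_level = 0.95) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  abort_if(sum(event) < 2, "need at least 2 events")
  abort_if(any(apply(X, 2, function(c) length(unique(c)) == 1)),
           "constant covariate")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(coef(fit))
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = colnames(X), beta = beta, se = se,
                    hr = exp(beta),
                    hr_lower = exp(beta - z * se),
                    hr_upper = exp(beta + z * se),
                    p_value = 2 * pnorm(-abs(beta / se)))
  attr(out, "converged") <- !flagged
  if (flagged) warning("Cox fit flagged: possible separation/non-convergence")
  out
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable pair, the subject with the higher risk
#' score fails first. Pairs are comparable when the earlier time is an
#' observed event (and times differ); score ties receive 0.5 credit.
#'
#' @param score higher = predicted to fail earlier.
#' @param time,event survival data.
#' @return C-index in \[0,1\], or NA when no pair is comparable.
#' @export
concordance_index <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  n <- length(time)
  if (n < 2) return(NA_real_)
  # vectorized over pairs (i earlier event, j later or censored-after)
  conc <- disc <- ties <- 0
  ev <- which(event == 1)
  for (i in ev) {
    comp <- time > time[i]
    if (!any(comp)) next
    d <- score[i] - score[comp]
    conc <- conc + sum(d > 0)
    disc <- disc + sum(d < 0)
    ties <- ties + sum(d == 0)
  }
  tot <- conc + disc + ties
  if (tot == 0) return(NA_real_)
  (conc + 0.5 * ties) / tot
}

#' Non-parametric group comparison
#'
#' Mann-Whitney U for two groups (U reported for the first group: number of
#' pairs where a first-group value exceeds a second-group value, i.e. the
#' `stats::wilcox.test` W convention), Kruskal-Wallis for three or more.
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @return list(test, statistic, p_value, n_groups).
#' @export
group_tests <- function(values, groups) {
  g <- as.factor(groups)
  abort_if(any(table(g) < 2), "every group needs at least 2 observations")
  if (nlevels(g) == 2) {
    wt <- suppressWarnings(wilcox.test(values[g == levels(g)[1]],
                                       values[g == levels(g)[2]]))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value, n_groups = 2L)
  } else {
    kt <- kruskal.test(values, g)
    list(test = "kruskal-wallis", statistic = unname(kt$statistic),
         p_value = kt$p.value, n_groups = nlevels(g))
  }
}

#' Correlation tests (Pearson and Spearman)
#' @param x,y paired numeric vectors.
#' @return data.frame with one row per method: estimate, p_value.
#' @export
assoc_tests <- function(x, y) {
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p_value = c(pe$p.value, sp$p.value))
}

#' Benjamini-Hochberg adjustment for a declared test family
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p_values) p.adjust(p_values, method = "BH")

#' Percentile bootstrap confidence interval
#'
#' @param data vector, matrix or data.frame (rows are resampled).
#' @param metric_fn function(data) -> scalar.
#' @param B number of resamples (>= 100; default 1000).
#' @param seed integer seed.
#' @param conf_level CI level.
#' @param max_redraw cap on redraws for resamples where the metric is
#'   undefined (NA/NaN/error).
#' @return list(estimate, lower, upper, B, n_redrawn).
#' @export
bootstrap_ci <- function(data, metric_fn, B = 1000, seed = 1L,
                         conf_level = 0.95, max_redraw = 1000) {
  abort_if(B < 100, "B must be >= 100")
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- function(idx) {
    if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  }
  est <- metric_fn(data)
  with_seed(seed, {
    vals <- numeric(B)
    redrawn <- 0
    for (b in seq_len(B)) {
      repeat {
        v <- tryCatch(metric_fn(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        redrawn <- redrawn + 1
        if (redrawn > max_redraw) {
          stop("metric undefined on too many bootstrap resamples")
        }
      }
      vals[b] <- v
    }
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(vals, c(a, 1 - a)))
    list(estimate = est, lower = ci[1], upper = ci[2], B = B,
         n_redrawn = redrawn)
  })
}
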