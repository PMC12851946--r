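# Independent oracles and shared fixtures. Oracles deliberately use naive
# enumeration / hand formulas, never the implementation under test.

# exhaustive Otsu: maximize between-class variance over all 255 cut points
oracle_otsu <- function(gray) {
  v <- as.integer(round(pmin(pmax(gray, 0), 1) * 255))
  best <- -1; best_k <- NA
  for (k in 1:255) {
    lo <- v[v < k]; hi <- v[v >= k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; best_k <- k }
  }
  (best_k - 0.5) / 255
}

# all-pairs Harrell concordance by double loop
oracle_concordance <- function(score, time, event) {
  n <- length(time)
  num <- den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# brute-force squared Euclidean distance to the nearest background pixel
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (!mask[r, c]) next
    out[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  out
}

# hand product-limit estimator
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# two-group log-rank by direct O-E/V tabulation at every event time
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t); n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + n1 * d / n
    if (n > 1) v <- v + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  (o1 - e1)^2 / v
}

# Mann-Whitney U for group x vs y by pair enumeration
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# Cox partial log-likelihood for a single binary covariate, no ties
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
  }
  ll
}

angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# cached small MIL model + its training bags (trained once per test run)
.test_cache <- new.env()
get_test_mil <- function() {
  if (is.null(.test_cache$mil)) {
    bags <- synth_mil_cohort(n_per_class = 8, tiles_per_bag = 10, seed = 1405)
    model <- train_mil(bags, mil_config(epochs = 5, lr = 3e-3, seed = 11))
    .test_cache$mil <- list(model = model, bags = bags)
  }
  .test_cache$mil
}

# cached mid-size fast-mode cohort + fitted risk model
get_test_risk <- function() {
  if (is.null(.test_cache$risk)) {
    co <- generate_cohort(cohort_spec(n_patients = 300, seed = 2024))
    ep <- composite_endpoint(co$clinical)
    fu <- fuse_features(co$clinical, co$features, co$class_probs,
                        co$expression)
    model <- train_risk(fu, ep$time, ep$event, n_rounds = 60, seed = 5)
    .test_cache$risk <- list(cohort = co, endpoint = ep, fused = fu,
                             model = model)
  }
  .test_cache$risk
}
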