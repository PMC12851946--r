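# Survival-augmented gradient boosting: regression trees fit to Cox
# partial-likelihood gradients (Breslow risk sets), maximizing concordance on
# the composite endpoint (first of death or major complication). Exact
# per-tree Shapley values and interaction values are computed in C++ by
# subset enumeration over each tree's feature set, so local accuracy
# (sum(phi) + base = margin) holds to machine precision.

RISK_BLOCKS <- c("subtype", "histologic", "clinical", "transcriptomic")

#' Default transcriptomic features fed to the risk model
#'
#' Individual immune-effector and inflammatory marker genes (z-scored).
#' Aggregate program scores are deliberately left out of the default risk
#' feature set so that attribution is per-marker; see the methods vignette.
#' @return character vector of gene symbols.
#' @export
default_risk_genes <- function() {
  pr <- default_gene_programs()
  unique(c(pr$immune, pr$inflammatory))
}

#' Fuse classifier, histologic, clinical and transcriptomic features
#'
#' Builds the numeric model matrix: subtype probabilities; the handcrafted
#' histomorphometry features; clinical covariates (sex one-hot to `sex_F`,
#' fracture level ordinal C < T < L < P, BMD T-score); z-scored expression of
#' selected marker genes. Missing transcriptomics stays missing-coded (NA,
#' handled natively by tree default directions), never zero-imputed.
#'
#' @param clinical clinical data.frame (see [generate_cohort()]).
#' @param features histomorphometry data.frame, same row order.
#' @param class_probs n x 3 matrix of subtype probabilities (or NULL).
#' @param expression genes x samples matrix; samples matched by patient_id
#'   column names (patients absent from it get NA transcriptomics).
#' @param genes marker genes to include (default [default_risk_genes()]).
#' @return list(X numeric matrix, manifest data.frame(column, block)).
#' @export
fuse_features <- function(clinical, features, class_probs = NULL,
                          expression = NULL, genes = default_risk_genes()) {
  n <- nrow(clinical)
  abort_if(n < 1, "need at least one record")
  blocks <- list()
  if (!is.null(class_probs)) {
    cp <- as.matrix(class_probs)
    colnames(cp) <- paste0("prob_", names(VCF_CLASSES))
    blocks$subtype <- cp
  }
  hist_cols <- setdiff(names(features), "microns_per_pixel")
  blocks$histologic <- as.matrix(features[, hist_cols, drop = FALSE])
  lev <- c(C = 1, T = 2, L = 3, P = 4)
  blocks$clinical <- cbind(
    age = clinical$age,
    sex_F = as.numeric(clinical$sex == "F"),
    fracture_level = unname(lev[clinical$fracture_level]),
    bmd_t = clinical$bmd_t
  )
  if (!is.null(expression)) {
    found <- intersect(genes, rownames(expression))
    if (length(found) < length(genes)) {
      warning(sprintf("%d risk genes absent from expression matrix",
                      length(genes) - length(found)))
    }
    tx <- matrix(NA_real_, n, length(found),
                 dimnames = list(NULL, paste0("expr_", found)))
    hit <- match(clinical$patient_id, colnames(expression))
    ok <- !is.na(hit)
    if (any(ok) && length(found)) {
      sub <- expression[found, hit[ok], drop = FALSE]
      # z-score each gene across the samples that have expression
      mu <- rowMeans(sub)
      sdv <- apply(sub, 1, sd)
      sdv[sdv == 0] <- 1
      tx[ok, ] <- t((sub - mu) / sdv)
    }
    blocks$transcriptomic <- tx
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  manifest <- data.frame(
    column = colnames(X),
    block = rep(names(blocks), vapply(blocks, ncol, integer(1)))
  )
  drop <- which(colSums(!is.na(X)) == 0)
  if (length(drop)) {
    warning("dropping all-missing columns: ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    manifest <- manifest[-drop, ]
  }
  list(X = X, manifest = manifest)
}

#' Composite time-to-first-event endpoint
#'
#' Earliest of death and major complication; a subject is an event if either
#' occurred, censored at last follow-up otherwise.
#' @param clinical clinical data.frame with time_months/event and
#'   complication_time_months/complication_event.
#' @return list(time, event).
#' @export
composite_endpoint <- function(clinical) {
  t1 <- clinical$time_months
  e1 <- clinical$event
  t2 <- clinical$complication_time_months %||% rep(Inf, nrow(clinical))
  e2 <- clinical$complication_event %||% rep(0L, nrow(clinical))
  t2e <- ifelse(e2 == 1, t2, Inf)
  time <- pmin(t1, t2e)
  event <- as.integer(e1 == 1 | (e2 == 1 & t2e <= t1))
  list(time = time, event = event)
}

# ---- Cox partial-likelihood gradients (Breslow) -----------------------------
cox_grad_hess <- function(margin, time, event) {
  n <- length(time)
  ord <- order(time)
  m <- margin[ord]; tt <- time[ord]; ev <- event[ord]
  em <- exp(m - max(m))
  # risk-set denominators R_k at each position (sum over j with t_j >= t_k),
  # shared across tied times
  rs <- rev(cumsum(rev(em)))
  first <- !duplicated(tt)
  rs_at <- rs[first][match(tt, tt[first])]
  # cumulative sums over event times u <= t_i of d_u / R_u and d_u / R_u^2
  inc1 <- ifelse(ev == 1, 1 / rs_at, 0)
  inc2 <- ifelse(ev == 1, 1 / rs_at^2, 0)
  c1 <- cumsum(inc1); c2 <- cumsum(inc2)
  last <- rev(!duplicated(rev(tt)))
  c1_at <- c1[last][match(tt, tt[last])]
  c2_at <- c2[last][match(tt, tt[last])]
  g <- -ev + em * c1_at
  h <- pmax(em * c1_at - em^2 * c2_at, 1e-12)
  out_g <- numeric(n); out_h <- numeric(n)
  out_g[ord] <- g; out_h[ord] <- h
  list(grad = out_g, hess = out_h)
}

# ---- regression tree on (g, h) with native missing-value routing ------------
build_tree <- function(X, g, h, max_depth, lambda, min_child_weight,
                       min_gain = 1e-6) {
  nodes <- new.env()
  nodes$feat <- integer(0); nodes$split <- numeric(0)
  nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$miss <- integer(0); nodes$value <- numeric(0)
  nodes$cover <- numeric(0)
  add_node <- function() {
    i <- length(nodes$feat) + 1L
    nodes$feat[i] <- -1L; nodes$split[i] <- 0; nodes$left[i] <- -1L
    nodes$right[i] <- -1L; nodes$miss[i] <- -1L; nodes$value[i] <- 0
    nodes$cover[i] <- 0
    i
  }
  grow <- function(idx, depth) {
    me <- add_node()
    G <- sum(g[idx]); H <- sum(h[idx])
    nodes$cover[me] <- length(idx)
    leaf_score <- G^2 / (H + lambda)
    best <- list(gain = min_gain)
    if (depth < max_depth && length(idx) >= 4) {
      for (j in seq_len(ncol(X))) {
        xj <- X[idx, j]
        na <- is.na(xj)
        if (all(na)) next
        o <- order(xj[!na])
        ii <- idx[!na][o]
        xs <- xj[!na][o]
        if (length(ii) < 2) next
        gl <- cumsum(g[ii]); hl <- cumsum(h[ii])
        Gna <- sum(g[idx[na]]); Hna <- sum(h[idx[na]])
        k <- which(diff(xs) > 0)
        if (!length(k)) next
        GL <- gl[k]; HL <- hl[k]
        GR <- (G - Gna) - GL; HR <- (H - Hna) - HL
        # NA routed left
        gain_l <- 0.5 * ((GL + Gna)^2 / (HL + Hna + lambda) +
                           GR^2 / (HR + lambda) - leaf_score)
        ok_l <- (HL + Hna) >= min_child_weight & HR >= min_child_weight
        gain_l[!ok_l] <- -Inf
        # NA routed right
        gain_r <- 0.5 * (GL^2 / (HL + lambda) +
                           (GR + Gna)^2 / (HR + Hna + lambda) - leaf_score)
        ok_r <- HL >= min_child_weight & (HR + Hna) >= min_child_weight
        gain_r[!ok_r] <- -Inf
        bi <- which.max(pmax(gain_l, gain_r))
        bg <- max(gain_l[bi], gain_r[bi])
        if (bg > best$gain) {
          best <- list(gain = bg, feature = j,
                       split = (xs[k[bi]] + xs[k[bi] + 1]) / 2,
                       na_left = gain_l[bi] >= gain_r[bi])
        }
      }
    }
    if (!is.null(best$feature)) {
      xj <- X[idx, best$feature]
      go_left <- !is.na(xj) & xj < best$split
      go_na <- is.na(xj)
      if (best$na_left) go_left <- go_left | go_na
      li <- grow(idx[go_left], depth + 1)
      ri <- grow(idx[!go_left], depth + 1)
      nodes$feat[me] <- best$feature - 1L
      nodes$split[me] <- best$split
      nodes$left[me] <- li - 1L
      nodes$right[me] <- ri - 1L
      nodes$miss[me] <- (if (best$na_left) li else ri) - 1L
    } else {
      nodes$value[me] <- -G / (H + lambda)
    }
    me
  }
  grow(seq_len(nrow(X)), 0)
  list(feat = nodes$feat, split = nodes$split, left = nodes$left,
       right = nodes$right, miss = nodes$miss, value = nodes$value,
       cover = nodes$cover)
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible())
    f <- tree$feat[node + 1]
    if (f < 0) {
      out[idx] <<- tree$value[node + 1]
      return(invisible())
    }
    xj <- X[idx, f + 1]
    na <- is.na(xj)
    left <- (!na & xj < tree$split[node + 1]) |
      (na & tree$miss[node + 1] == tree$left[node + 1])
    rec(tree$left[node + 1], idx[left])
    rec(tree$right[node + 1], idx[!left])
  }
  rec(0L, seq_len(nrow(X)))
  out
}

boost_cox <- function(X, time, event, n_rounds, eta, max_depth, lambda,
                      min_child_weight) {
  n <- nrow(X)
  margin <- numeric(n)
  trees <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    gh <- cox_grad_hess(margin, time, event)
    tr <- build_tree(X, gh$grad, gh$hess, max_depth, lambda,
                     min_child_weight)
    tr$value <- tr$value * eta
    trees[[r]] <- tr
    margin <- margin + predict_tree(tr, X)
  }
  list(trees = trees, margin = margin)
}

predict_margin <- function(trees, X) {
  m <- numeric(nrow(X))
  for (tr in trees) m <- m + predict_tree(tr, X)
  m
}

#' Train the gradient-boosted survival risk model
#'
#' Boosted regression trees on Cox partial-likelihood gradients over the
#' composite endpoint. Reports the 5-fold cross-validated C-index, refits on
#' the full training set, and calibrates the monotone margin-to-\[0,1\] map
#' (logistic centred at the training-margin median, scaled by its IQR) plus
#' the training tertile cut points for low/intermediate/high groups.
#'
#' @param fused a [fuse_features()] result.
#' @param time,event composite endpoint (see [composite_endpoint()]).
#' @param n_rounds boosting rounds (default 120).
#' @param eta learning rate (default 0.1).
#' @param max_depth tree depth cap (default 3; kept small to limit
#'   memorization).
#' @param lambda L2 leaf regularization.
#' @param min_child_weight minimum hessian sum per child.
#' @param cv_folds folds for cross-validation (default 5).
#' @param seed fold-assignment seed.
#' @return object of class `risk_model`.
#' @export
train_risk <- function(fused, time, event, n_rounds = 120, eta = 0.1,
                       max_depth = 3, lambda = 1, min_child_weight = 3,
                       cv_folds = 5, seed = 1L) {
  X <- fused$X
  abort_if(sum(event) < 2, "need at least 2 events to train")
  n <- nrow(X)
  folds <- with_seed(derive_seed(seed, "cv"), sample(rep_len(seq_len(cv_folds), n)))
  cv_c <- numeric(cv_folds)
  oof_margin <- numeric(n)
  for (f in seq_len(cv_folds)) {
    tr_i <- which(folds != f); te_i <- which(folds == f)
    fit <- boost_cox(X[tr_i, , drop = FALSE], time[tr_i], event[tr_i],
                     n_rounds, eta, max_depth, lambda, min_child_weight)
    m_te <- predict_margin(fit$trees, X[te_i, , drop = FALSE])
    oof_margin[te_i] <- m_te
    cv_c[f] <- concordance_index(m_te, time[te_i], event[te_i])
  }
  fit <- boost_cox(X, time, event, n_rounds, eta, max_depth, lambda,
                   min_child_weight)
  med <- median(fit$margin)
  iqr <- max(stats::IQR(fit$margin), 1e-8)
  risk <- plogis((fit$margin - med) / iqr)
  cuts <- unname(quantile(risk, c(1 / 3, 2 / 3), type = 1))
  structure(list(
    trees = fit$trees,
    feature_names = colnames(X),
    manifest = fused$manifest,
    scaler = c(median = med, iqr = iqr),
    tertiles = cuts,
    cv_cindex = cv_c,
    cv_cindex_mean = mean(cv_c),
    oof_margin = oof_margin,
    folds = folds,
    params = list(n_rounds = n_rounds, eta = eta, max_depth = max_depth,
                  lambda = lambda, min_child_weight = min_child_weight,
                  cv_folds = cv_folds, seed = seed),
    train_margin = fit$margin
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d trees, %d features; CV C-index %.3f\n",
              length(x$trees), length(x$feature_names), x$cv_cindex_mean))
  invisible(x)
}

#' Score patients with a trained risk model
#'
#' @param model a [train_risk()] model.
#' @param X model matrix with the model's feature columns.
#' @return data.frame(margin, risk_score, risk_group) where risk_score is in
#'   \[0,1\] and groups are the training-set tertiles (low/intermediate/high).
#' @export
score_risk <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$feature_names, colnames(X))
  abort_if(length(missing) > 0,
           paste("missing feature columns:", paste(missing, collapse = ", ")))
  X <- X[, model$feature_names, drop = FALSE]
  m <- predict_margin(model$trees, X)
  risk <- plogis((m - model$scaler["median"]) / model$scaler["iqr"])
  grp <- cut(risk, c(-Inf, model$tertiles, Inf),
             labels = c("low", "intermediate", "high"))
  data.frame(margin = m, risk_score = unname(risk), risk_group = grp)
}

#' Exact SHAP values and interactions for a risk model
#'
#' Per-tree Shapley values by exhaustive subset enumeration over each tree's
#' used features (trees are depth-limited, so this is exact and fast).
#' Satisfies local accuracy `rowSums(phi) + base == margin` and the
#' interaction row-sum identity exactly.
#'
#' @param model a [train_risk()] model.
#' @param X model matrix.
#' @param interactions also compute the feature x feature interaction arrays
#'   (default TRUE).
#' @return list(phi (n x p), base (n), interactions (p x p x n or NULL),
#'   importance data.frame ranked by mean |SHAP|).
#' @export
explain_shap <- function(model, X, interactions = TRUE) {
  X <- as.matrix(X)[, model$feature_names, drop = FALSE]
  res <- cpp_tree_shap(model$trees, X, length(model$feature_names),
                       interactions)
  colnames(res$phi) <- model$feature_names
  imp <- data.frame(feature = model$feature_names,
                    mean_abs_shap = colMeans(abs(res$phi)))
  imp <- imp[order(-imp$mean_abs_shap), ]
  rownames(imp) <- NULL
  list(phi = res$phi, base = res$base,
       interactions = if (interactions) res$interactions else NULL,
       importance = imp)
}

#' Feature-block ablation
#'
#' Retrains with identical folds after dropping one feature block and
#' reports the paired CV C-index difference with a percentile bootstrap CI
#' over the pooled out-of-fold predictions.
#'
#' @param fused a [fuse_features()] result.
#' @param time,event composite endpoint.
#' @param drop_block one of "subtype", "histologic", "clinical",
#'   "transcriptomic".
#' @param seed seed (must match the full model's for paired folds).
#' @param B bootstrap resamples.
#' @param ... passed to [train_risk()].
#' @return list(full, reduced (models), delta_cindex, ci, per_fold).
#' @export
ablate <- function(fused, time, event, drop_block, seed = 1L, B = 500, ...) {
  drop_block <- match.arg(drop_block, RISK_BLOCKS)
  keep <- fused$manifest$block != drop_block
  abort_if(!any(keep), "cannot drop every feature block")
  abort_if(all(keep), paste("no columns in block", drop_block))
  reduced <- list(X = fused$X[, keep, drop = FALSE],
                  manifest = fused$manifest[keep, ])
  full_m <- train_risk(fused, time, event, seed = seed, ...)
  red_m <- train_risk(reduced, time, event, seed = seed, ...)
  stopifnot(identical(full_m$folds, red_m$folds))
  d <- full_m$cv_cindex_mean - red_m$cv_cindex_mean
  df <- data.frame(mf = full_m$oof_margin, mr = red_m$oof_margin,
                   time = time, event = event)
  bs <- bootstrap_ci(df, function(dd) {
    concordance_index(dd$mf, dd$time, dd$event) -
      concordance_index(dd$mr, dd$time, dd$event)
  }, B = B, seed = derive_seed(seed, "ablate"))
  list(full = full_m, reduced = red_m, drop_block = drop_block,
       delta_cindex = d, ci = c(bs$lower, bs$upper),
       per_fold = data.frame(fold = seq_along(full_m$cv_cindex),
                             full = full_m$cv_cindex,
                             reduced = red_m$cv_cindex))
}
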