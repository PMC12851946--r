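# Transcriptomic scoring: expression loading/validation, immune activity,
# therapy-sensitivity signature scores, responder binarization, and combined
# risk/immune stratification.

#' Define a gene set
#' @param name set name.
#' @param genes character vector of unique gene symbols.
#' @param weights direction weights (+1/-1), default all +1.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, weights = NULL) {
  abort_if(length(genes) == 0, "gene set must be non-empty")
  abort_if(anyDuplicated(genes) > 0, "gene symbols must be unique")
  w <- weights %||% rep(1, length(genes))
  stopifnot(length(w) == length(genes))
  structure(list(name = name, genes = genes, weights = w),
            class = "gene_set")
}

#' Packaged default signature gene sets
#'
#' Illustrative defaults (editable JSON under `inst/extdata/gene_sets.json`):
#' immune effectors, RANKL axis (anti-resorptive response), steroid response,
#' chemotherapy response/proliferation.
#' @return named list of [gene_set()]s.
#' @export
default_gene_sets <- function() {
  path <- system.file("extdata", "gene_sets.json", package = "spinepath")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) gene_set(x$name, x$genes, x$weights))
}

#' Load and validate a genes x samples expression TSV
#'
#' First column = gene symbol, remaining columns numeric samples.
#'
#' @param path TSV file.
#' @param log2_transform apply log2(x + 1).
#' @return numeric matrix (genes x samples).
#' @export
load_expression <- function(path, log2_transform = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(df) < 2, "expression TSV needs a gene column plus samples")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  abort_if(length(dup) > 0,
           paste("duplicate gene symbols:", paste(unique(dup), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (is.character(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   genes[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
    }
    m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  }
  abort_if(anyNA(m), "expression matrix contains missing values")
  rownames(m) <- genes
  if (log2_transform) m <- log2(m + 1)
  m
}

#' Per-gene z-scoring across samples
#' @param expr genes x samples matrix.
#' @return z-scored matrix; constant genes become all-zero with a warning.
#' @export
zscore_expression <- function(expr) {
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sprintf("%d constant gene(s): z-scores set to 0", sum(flat)))
    sdv[flat] <- 1
  }
  (expr - mu) / sdv
}

# shared overlap resolution with the >= min_overlap warning policy
resolve_set <- function(expr, set, min_overlap = 0.5) {
  found <- intersect(set$genes, rownames(expr))
  abort_if(length(found) == 0,
           sprintf("no genes of set '%s' present in the matrix", set$name))
  if (length(found) < length(set$genes)) {
    frac <- length(found) / length(set$genes)
    msg <- sprintf("set '%s': %d/%d genes present", set$name,
                   length(found), length(set$genes))
    if (frac < min_overlap) {
      warning(paste(msg, "(below minimum overlap)"))
    } else message(msg)
  }
  w <- set$weights[match(found, set$genes)]
  list(genes = found, weights = w)
}

#' Immune Activity Score
#'
#' Per-sample mean expression of the immune effector gene set (optionally of
#' the z-scored matrix).
#'
#' @param expr genes x samples matrix.
#' @param immune_set a [gene_set()]; default packaged immune set.
#' @param zscore z-score genes first (default FALSE: plain mean expression).
#' @return named numeric vector, one score per sample.
#' @export
immune_activity_score <- function(expr, immune_set = default_gene_sets()$immune,
                                  zscore = FALSE) {
  rs <- resolve_set(expr, immune_set)
  m <- if (zscore) zscore_expression(expr) else expr
  colMeans(m[rs$genes, , drop = FALSE])
}

#' Direction-weighted signature score
#'
#' `sum(w_g * x_g) / |set|` over the member genes found in the matrix, by
#' default on the z-scored matrix. With all +1 weights and `zscore = FALSE`
#' this reduces to [immune_activity_score()].
#'
#' @param expr genes x samples matrix.
#' @param set a [gene_set()].
#' @param zscore use per-gene z-scores (default TRUE).
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, set, zscore = TRUE) {
  rs <- resolve_set(expr, set)
  m <- if (zscore) zscore_expression(expr) else expr
  as.numeric(rs$weights %*% m[rs$genes, , drop = FALSE]) / length(rs$genes) ->
    s
  setNames(s, colnames(expr))
}

#' Binarize signature scores into responder flags
#'
#' A sample is a responder when its score is strictly above the threshold
#' (scores exactly at the threshold are non-responders; documented tie rule).
#' Thresholds default to the cohort median.
#'
#' @param scores named numeric vector.
#' @param threshold numeric threshold, or NULL for the cohort median.
#' @return list(responder (logical, NA where score missing), rule (serialized
#'   description sufficient to reproduce the flags)).
#' @export
classify_responder <- function(scores, threshold = NULL) {
  thr <- threshold %||% median(scores, na.rm = TRUE)
  flags <- ifelse(is.na(scores), NA, scores > thr)
  list(responder = flags,
       rule = list(comparison = "score > threshold", threshold = thr,
                   tie_rule = "score == threshold is non-responder",
                   source = if (is.null(threshold)) "cohort median" else
                     "supplied"))
}

#' All omics scores for a cohort
#'
#' @param expr genes x samples matrix.
#' @param sets list of gene sets (default packaged sets).
#' @param thresholds optional named list of responder thresholds.
#' @return data.frame(sample, immune_activity, rankl_score, steroid_score,
#'   chemo_score, responder) with attribute `rules` (serialized thresholds).
#' @export
omics_scores <- function(expr, sets = default_gene_sets(),
                         thresholds = NULL) {
  ia <- immune_activity_score(expr, sets$immune)
  rk <- signature_score(expr, sets$rankl)
  st <- signature_score(expr, sets$steroid)
  chm <- signature_score(expr, sets$chemo)
  rk_resp <- classify_responder(rk, thresholds$rankl %||% NULL)
  st_resp <- classify_responder(st, thresholds$steroid %||% NULL)
  chm_resp <- classify_responder(chm, thresholds$chemo %||% NULL)
  out <- data.frame(sample = colnames(expr),
                    immune_activity = unname(ia),
                    rankl_score = unname(rk),
                    steroid_score = unname(st),
                    chemo_score = unname(chm),
                    responder = unname(rk_resp$responder))
  attr(out, "rules") <- list(rankl = rk_resp$rule, steroid = st_resp$rule,
                             chemo = chm_resp$rule)
  out
}

#' Combined risk/immune strata
#'
#' Splits patients into the four quadrants low-risk/high-immune,
#' low-risk/low-immune, high-risk/high-immune, high-risk/low-immune by
#' median (or supplied) cut points. Rank-based, so invariant to monotone
#' transforms of either score.
#'
#' @param risk named numeric risk scores.
#' @param immune named numeric immune scores (same names).
#' @param cutpoints optional c(risk = , immune = ) cut points.
#' @return factor of strata labels aligned with `risk`.
#' @export
risk_immune_strata <- function(risk, immune, cutpoints = NULL) {
  if (!is.null(names(risk)) && !is.null(names(immune))) {
    abort_if(!identical(sort(names(risk)), sort(names(immune))),
             "risk and immune scores refer to different samples")
    immune <- immune[names(risk)]
  } else {
    abort_if(length(risk) != length(immune), "misaligned score vectors")
  }
  rc <- if (is.null(cutpoints)) median(risk) else cutpoints[["risk"]]
  ic <- if (is.null(cutpoints)) median(immune) else cutpoints[["immune"]]
  hr <- risk > rc
  hi <- immune > ic
  labs <- ifelse(hr & hi, "high-risk/high-immune",
          ifelse(hr & !hi, "high-risk/low-immune",
          ifelse(!hr & hi, "low-risk/high-immune", "low-risk/low-immune")))
  factor(labs, levels = c("low-risk/high-immune", "low-risk/low-immune",
                          "high-risk/high-immune", "high-risk/low-immune"))
}
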