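# Seeded cohort generator: class labels, clinical covariates, per-patient
# morphometry (fast mode draws the true feature values from class-conditional
# distributions calibrated on rendered slides; render mode actually renders
# slides), a gene-expression matrix whose immune/inflammatory programs
# co-vary with a latent risk, and right-censored Weibull survival driven by
# that risk. Every latent quantity is kept as ground truth.

#' Default gene program definitions
#' @return named list of character vectors (gene symbols).
#' @export
default_gene_programs <- function() {
  list(
    immune = c("GZMB", "IFNG", "CD8A", "PRF1", "CXCL13"),
    inflammatory = c("TNF", "IL1B", "IL6", "NFKB1", "PTGS2"),
    rankl = c("TNFSF11", "TNFRSF11B", "TNF"),
    steroid = c("NR3C1", "FKBP5", "TSC22D3"),
    chemo = c("MKI67", "TOP2A", "TYMS", "AURKA"),
    remodeling = c("COL1A1", "SPP1", "BGLAP", "RUNX2")
  )
}

# fixed class-conditional feature distributions (means calibrated once on
# rendered default slides; see the methods vignette) and fixed population
# scalers used by the latent-risk model
fastmode_params <- function() {
  list(
    means = list(
      osteoporotic = c(bf = 0.116, th = 62, sep = 330, ost = 75, adip = 0.40,
                       coll = 0.033, infl = 92, ecc = 0.36, disr = 70,
                       fibr = 0.066),
      traumatic    = c(bf = 0.264, th = 100, sep = 160, ost = 75, adip = 0.19,
                       coll = 0.061, infl = 187, ecc = 0.44, disr = 45,
                       fibr = 0.122),
      neoplastic   = c(bf = 0.210, th = 95, sep = 180, ost = 75, adip = 0.045,
                       coll = 0.158, infl = 138, ecc = 0.51, disr = 50,
                       fibr = 0.316)
    ),
    sds = c(bf = 0.02, th = 8, sep = 30, ost = 10, adip = 0.04, coll = 0.018,
            infl = 28, ecc = 0.07, disr = 10, fibr = 0.05),
    # population scalers for z-scores in the latent risk model
    ref = list(ecc = c(0.437, 0.08), coll = c(0.084, 0.05),
               th = c(86, 20), infl = c(139, 45), risk_lin = c(0, 1.7))
  )
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate a 150-case vertebral compression fracture cohort split
#' 60/50/40 between osteoporotic, traumatic and neoplastic fractures (exact
#' largest-remainder apportionment), with a latent severity built from the
#' planted morphometry (nucleus eccentricity carrying three times the weight
#' of any other feature), an immune activation latent coupled to severity,
#' and Weibull proportional-hazards survival with independent exponential
#' censoring.
#'
#' @param n_patients cohort size (>= 2).
#' @param class_proportions length-3 proportions (osteoporotic, traumatic,
#'   neoplastic) summing to 1.
#' @param hazard_beta log hazard ratio per standard deviation of the latent
#'   risk linear predictor (default 1.5).
#' @param censoring_rate target fraction of censored subjects in \[0, 1).
#' @param followup_cap_months administrative censoring horizon (default 60).
#' @param n_noise_genes extra pure-noise genes in the expression matrix.
#' @param mode "fast" (draw true morphometry directly) or "render" (render
#'   slides and keep them; much slower).
#' @param image_px slide size when rendering.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 150,
                        class_proportions = c(0.4, 1 / 3, 4 / 15),
                        hazard_beta = 1.5,
                        censoring_rate = 0.3,
                        followup_cap_months = 60,
                        n_noise_genes = 96,
                        mode = c("fast", "render"),
                        image_px = 320,
                        seed = 1L) {
  abort_if(n_patients < 2, "n_patients must be >= 2")
  abort_if(abs(sum(class_proportions) - 1) > 1e-6,
           "class_proportions must sum to 1")
  abort_if(censoring_rate < 0 || censoring_rate >= 1,
           "censoring_rate must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 class_proportions = class_proportions,
                 hazard_beta = hazard_beta,
                 censoring_rate = censoring_rate,
                 followup_cap_months = followup_cap_months,
                 n_noise_genes = as.integer(n_noise_genes),
                 mode = match.arg(mode),
                 image_px = as.integer(image_px),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with:
#'   \describe{
#'     \item{clinical}{data.frame: patient_id, fracture_class, class_code,
#'       age, sex, fracture_level, bmd_t, time_months, event,
#'       complication_time_months, complication_event.}
#'     \item{features}{data.frame of per-patient histomorphometry (fast-mode
#'       truth or measured from rendered slides).}
#'     \item{class_probs}{n x 3 matrix of soft subtype probabilities
#'       (stand-in for the MIL classifier within desk-scale runs).}
#'     \item{expression}{genes x samples matrix (log2-like scale).}
#'     \item{truth}{data.frame of latent ground truth: latent_risk (0-1),
#'       risk_lin, z_severity, z_immune.}
#'     \item{slides}{render mode only: list of render_slide() results.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  counts <- apportion(n, spec$class_proportions)
  classes <- rep(names(VCF_CLASSES), counts)
  classes <- sample(classes)                     # shuffle patient order
  pid <- sprintf("P%04d", seq_len(n))
  pars <- fastmode_params()

  # --- clinical covariates ---
  age_mu <- c(osteoporotic = 74, traumatic = 58, neoplastic = 66)
  age_sd <- c(osteoporotic = 9, traumatic = 14, neoplastic = 10)
  p_female <- c(osteoporotic = 0.65, traumatic = 0.45, neoplastic = 0.5)
  age <- clamp(rnorm(n, age_mu[classes], age_sd[classes]), 25, 95)
  sex <- ifelse(runif(n) < p_female[classes], "F", "M")
  level <- sample(c("C", "T", "L", "P"), n, replace = TRUE,
                  prob = c(0.05, 0.45, 0.45, 0.05))
  bmd_mu <- c(osteoporotic = -3.1, traumatic = -0.8, neoplastic = -1.2)
  bmd_sd <- c(osteoporotic = 0.6, traumatic = 1.0, neoplastic = 1.0)
  bmd_t <- rnorm(n, bmd_mu[classes], bmd_sd[classes])

  # --- morphometry ---
  slides <- NULL
  if (spec$mode == "render") {
    slides <- vector("list", n)
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      sl_seed <- derive_seed(spec$seed, paste0("slide", i))
      sp <- slide_spec(classes[i], image_size = c(spec$image_px, spec$image_px),
                       seed = sl_seed)
      slides[[i]] <- render_slide(sp)
      feats[[i]] <- compute_histomorphometry(slides[[i]]$image,
                                             sp$microns_per_pixel,
                                             slides[[i]]$truth$masks$tissue)
    }
    features <- do.call(rbind, feats)
  } else {
    mu <- do.call(rbind, pars$means[classes])
    sd_ <- pars$sds
    draw <- function(key, lo = -Inf, hi = Inf) {
      clamp(rnorm(n, mu[, key], sd_[key]), lo, hi)
    }
    features <- data.frame(
      trabecular_bone_fraction = draw("bf", 0.01, 0.9),
      trabecular_thickness_um = draw("th", 10),
      trabecular_separation_um = draw("sep", 20),
      osteocyte_density_per_mm2 = draw("ost", 0),
      marrow_adiposity_fraction = draw("adip", 0, 0.9),
      collagen_density_fraction = draw("coll", 0, 0.9),
      inflammatory_cell_density_per_mm2 = draw("infl", 0),
      nucleus_eccentricity_mean = draw("ecc", 0.02, 0.97),
      trabecular_disruption_score = draw("disr", 0),
      marrow_fibrosis_score = clamp(draw("coll", 0, 0.9) / 0.5, 0, 1),
      microns_per_pixel = rep(4, n)
    )
  }

  # --- soft subtype probabilities (classifier stand-in) ---
  conc <- matrix(1, n, 3)
  conc[cbind(seq_len(n), match(classes, names(VCF_CLASSES)))] <- 14
  gam <- matrix(rgamma(n * 3, shape = as.numeric(conc)), n, 3)
  class_probs <- gam / rowSums(gam)
  colnames(class_probs) <- paste0("prob_", names(VCF_CLASSES))

  # --- latent severity, immune activation, risk ---
  ref <- pars$ref
  z <- function(x, key) (x - ref[[key]][1]) / ref[[key]][2]
  z_ecc <- z(features$nucleus_eccentricity_mean, "ecc")
  z_coll <- z(features$collagen_density_fraction, "coll")
  z_th <- z(features$trabecular_thickness_um, "th")
  z_infl <- z(features$inflammatory_cell_density_per_mm2, "infl")
  z_sev <- (1.5 * z_ecc + 0.5 * z_coll - 0.5 * z_th + 0.3 * z_infl) / 1.68
  z_imm <- 0.6 * z_sev + 0.8 * rnorm(n)
  risk_lin <- 0.7 * z_sev + 1.2 * z_imm + 0.15 * rnorm(n)
  latent_risk <- plogis(risk_lin / 1.9)
  z_rl <- (risk_lin - ref$risk_lin[1]) / ref$risk_lin[2]

  # --- survival: Weibull PH + independent exponential censoring + cap ---
  k_shape <- 1.3
  lambda0 <- 30 / log(2)^(1 / k_shape)    # median 30 months at z_rl = 0
  death_t <- lambda0 * (-log(runif(n)) / exp(spec$hazard_beta * z_rl))^(1 / k_shape)
  cap <- spec$followup_cap_months
  if (spec$censoring_rate > 0) {
    crate <- calibrate_censoring(spec, k_shape, lambda0, z_rl)
    cens_t <- pmin(rexp(n, rate = crate), cap)
  } else {
    cens_t <- rep(Inf, n)
  }
  time_months <- pmax(0.25, pmin(death_t, cens_t))
  event <- as.integer(death_t <= cens_t)
  # complication / re-fracture: a second proportional-hazards process driven
  # by the same latent risk, observed only within the first 12 months
  k_comp <- 1.1
  lambda_c <- 24 / log(2)^(1 / k_comp)    # median 24 months at z_rl = 0
  comp_t_lat <- lambda_c *
    (-log(runif(n)) / exp(spec$hazard_beta * z_rl))^(1 / k_comp)
  horizon <- pmin(12, time_months)
  comp_event <- as.integer(comp_t_lat <= horizon)
  comp_time <- pmin(comp_t_lat, horizon)

  # --- expression matrix ---
  programs <- default_gene_programs()
  genes <- unique(unlist(programs))
  noise_genes <- sprintf("GENE%03d", seq_len(spec$n_noise_genes))
  all_genes <- c(genes, noise_genes)
  expr <- matrix(rnorm(length(all_genes) * n, 7, 1), length(all_genes), n,
                 dimnames = list(all_genes, pid))
  is_osteo <- as.numeric(classes == "osteoporotic")
  is_neo <- as.numeric(classes == "neoplastic")
  z_ster <- rnorm(n)
  expr[programs$immune, ] <- expr[programs$immune, ] +
    matrix(1.0 * z_imm, length(programs$immune), n, byrow = TRUE)
  expr[programs$inflammatory, ] <- expr[programs$inflammatory, ] +
    matrix(0.6 * z_imm, length(programs$inflammatory), n, byrow = TRUE)
  expr[programs$rankl, ] <- expr[programs$rankl, ] +
    matrix(0.8 * is_osteo, length(programs$rankl), n, byrow = TRUE)
  expr[programs$steroid, ] <- expr[programs$steroid, ] +
    matrix(0.8 * z_ster, length(programs$steroid), n, byrow = TRUE)
  expr[programs$chemo, ] <- expr[programs$chemo, ] +
    matrix(1.2 * is_neo, length(programs$chemo), n, byrow = TRUE)
  expr[programs$remodeling, ] <- expr[programs$remodeling, ] +
    matrix(0.5 * z_coll, length(programs$remodeling), n, byrow = TRUE)
  expr <- pmax(expr, 0)

  clinical <- data.frame(
    patient_id = pid,
    fracture_class = classes,
    class_code = unname(VCF_CLASSES[classes]),
    age = age, sex = sex, fracture_level = level, bmd_t = bmd_t,
    time_months = time_months, event = event,
    complication_time_months = comp_time, complication_event = comp_event
  )
  truth <- data.frame(patient_id = pid, latent_risk = latent_risk,
                      risk_lin = risk_lin, z_severity = z_sev,
                      z_immune = z_imm, z_steroid = z_ster,
                      death_time = death_t)
  out <- list(clinical = clinical, features = features,
              class_probs = class_probs, expression = expr, truth = truth,
              spec = spec)
  if (!is.null(slides)) out$slides <- slides
  out
}

# bisect the exponential censoring rate so that P(censored) matches the
# target under the cohort's survival model, using the cohort's actual latent
# risk distribution (internal Monte Carlo on a derived seed; deterministic)
calibrate_censoring <- function(spec, k_shape, lambda0, z_rl) {
  target <- spec$censoring_rate
  cap <- spec$followup_cap_months
  m <- 4000
  sim <- with_seed(derive_seed(spec$seed, "censor-cal"), {
    z <- sample(z_rl, m, replace = TRUE)
    tt <- lambda0 * (-log(runif(m)) / exp(spec$hazard_beta * z))^(1 / k_shape)
    u <- runif(m)
    list(tt = tt, u = u)
  })
  frac_cens <- function(rate) {
    ct <- pmin(-log(sim$u) / rate, cap)
    mean(ct < sim$tt)
  }
  lo <- 1e-5; hi <- 2
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    if (frac_cens(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Write a cohort to disk (CSV/TSV/JSON artifacts)
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "clinical.csv")
  write.csv(cohort$clinical, f1, row.names = FALSE)
  f2 <- file.path(dir, "features.csv")
  write.csv(cbind(patient_id = cohort$clinical$patient_id, cohort$features),
            f2, row.names = FALSE)
  f3 <- file.path(dir, "expression.tsv")
  df <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                   check.names = FALSE)
  write.table(df, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  f4 <- file.path(dir, "ground_truth.csv")
  write.csv(cohort$truth, f4, row.names = FALSE)
  f5 <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    n_patients = cohort$spec$n_patients,
    class_counts = as.list(table(cohort$clinical$fracture_class)),
    seed = cohort$spec$seed, mode = cohort$spec$mode,
    files = c("clinical.csv", "features.csv", "expression.tsv",
              "ground_truth.csv")
  ), f5, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(f1, f2, f3, f4, f5))
}
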