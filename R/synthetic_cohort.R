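#' Synthetic phantom cohort for axillary nodal-status modeling
#'
#' A seeded generator for a phantom breast-cancer cohort: a clinical table
#' with 11 preoperative predictors and 5 postoperative outcomes whose
#' conditional structure (by nodal status) mirrors a published supervised-
#' learning cohort, plus multi-view phantom mammograms in which the lesion
#' geometry encodes tumor size and multifocality and a peritumoral
#' spiculation halo encodes LNM/LVI signal extending beyond the tumor ROI.
#' Everything is deterministic given the configuration seed.
#'
#' @name synthetic_cohort
NULL

#' Cohort generator configuration
#'
#' Defaults encode the study conditions the generator emulates: 30% LNM
#' prevalence; pathological tumor size with conditional means 18.9 mm
#' (node-positive) and 14.2 mm (node-negative), SD 8.1 mm, truncated to
#' (0, 50] mm; LVI positive rates 33%/11% by nodal status; multifocality
#' rates 34%/19%; number of metastatic nodes 1 + negative-binomial with
#' mean 2.4 and SD 2.8 among positives and exactly 0 among negatives;
#' 2 views per patient. Desk-scale images are 384 x 256 px at 2 px/mm.
#'
#' @param n_patients Number of patients.
#' @param prevalence_lnm Probability of nodal positivity.
#' @param size_mean_pos,size_mean_neg,size_sd Tumor size distribution (mm).
#' @param lvi_rate_pos,lvi_rate_neg LVI positive rate by nodal status.
#' @param multifoc_rate_pos,multifoc_rate_neg Multifocality rate by status.
#' @param nlnm_mean_pos,nlnm_sd_pos Mean/SD of the number of metastatic
#'   nodes among node-positive patients.
#' @param views_per_patient Views rendered per patient (1, 2 or 3).
#' @param image_height,image_width Phantom image size in pixels.
#' @param px_per_mm Pixel pitch.
#' @param peritumoral_signal_strength Non-negative scale of the planted
#'   peritumoral halo; 0 switches the image LNM/LVI signal off.
#' @param halo_inner_mm,halo_width_mm Halo annulus geometry, measured
#'   outward from the lesion margin.
#' @param missing_rates Named list of per-variable MCAR missingness rates
#'   (defaults mirror the emulated cohort's missing counts, e.g. LVI ~12.5%).
#' @param null_associations When `TRUE`, every covariate and outcome other
#'   than LNM itself is drawn from its pooled marginal distribution,
#'   independent of nodal status -- a null cohort for type-I-error and
#'   effect-size calibration checks.
#' @param seed Integer seed; the entire cohort (tables and images) is a
#'   deterministic function of the configuration including this seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1200,
                          prevalence_lnm = 0.30,
                          size_mean_pos = 18.9,
                          size_mean_neg = 14.2,
                          size_sd = 8.1,
                          lvi_rate_pos = 0.33,
                          lvi_rate_neg = 0.11,
                          multifoc_rate_pos = 0.34,
                          multifoc_rate_neg = 0.19,
                          nlnm_mean_pos = 2.4,
                          nlnm_sd_pos = 2.8,
                          views_per_patient = 2,
                          image_height = 384,
                          image_width = 256,
                          px_per_mm = 2,
                          peritumoral_signal_strength = 1,
                          halo_inner_mm = 2,
                          halo_width_mm = 25,
                          missing_rates = NULL,
                          null_associations = FALSE,
                          seed = 1) {
  probs <- c(prevalence_lnm, lvi_rate_pos, lvi_rate_neg,
             multifoc_rate_pos, multifoc_rate_neg)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all rates must be probabilities in [0, 1]")
  if (!(size_mean_pos > size_mean_neg && size_mean_neg > 0))
    stop("need size_mean_pos > size_mean_neg > 0")
  if (size_sd <= 0) stop("size_sd must be positive")
  if (!views_per_patient %in% 1:3) stop("views_per_patient must be 1, 2 or 3")
  if (peritumoral_signal_strength < 0)
    stop("peritumoral_signal_strength must be >= 0")
  mr <- list(age = 0, bmi = 0.032, menopausal = 0.044, detection_mode = 0,
             grade = 0.010, histotype = 0, er = 0.003, pgr = 0.003,
             her2 = 0.052, ki67 = 0.036, outcome_lvi = 0.125,
             outcome_tsize = 0, outcome_multifoc = 0)
  if (!is.null(missing_rates)) {
    bad <- setdiff(names(missing_rates), names(mr))
    if (length(bad)) stop("unknown missing_rates entries: ",
                          paste(bad, collapse = ", "))
    mr[names(missing_rates)] <- missing_rates
  }
  if (any(unlist(mr) < 0 | unlist(mr) > 1))
    stop("missing rates must be probabilities in [0, 1]")
  structure(list(
    n_patients = n_patients, prevalence_lnm = prevalence_lnm,
    size_mean_pos = size_mean_pos, size_mean_neg = size_mean_neg,
    size_sd = size_sd, lvi_rate_pos = lvi_rate_pos,
    lvi_rate_neg = lvi_rate_neg, multifoc_rate_pos = multifoc_rate_pos,
    multifoc_rate_neg = multifoc_rate_neg, nlnm_mean_pos = nlnm_mean_pos,
    nlnm_sd_pos = nlnm_sd_pos, views_per_patient = views_per_patient,
    image_height = image_height, image_width = image_width,
    px_per_mm = px_per_mm,
    peritumoral_signal_strength = peritumoral_signal_strength,
    halo_inner_mm = halo_inner_mm, halo_width_mm = halo_width_mm,
    missing_rates = mr, null_associations = isTRUE(null_associations),
    seed = seed), class = "cohort_config")
}

# truncated normal on (lo, hi] by rejection (vectorized)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean[todo], sd)
    ok <- draw > lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

rcat <- function(n, levels, prob) {
  levels[1 + findInterval(stats::runif(n), cumsum(prob)[-length(prob)],
                          left.open = FALSE)]
}

#' Generate a phantom clinical cohort
#'
#' Draws patient records per the configured conditional distributions:
#' nodal status is Bernoulli(prevalence); tumor size is truncated-normal on
#' (0, 50] mm with status-conditional means; LVI and multifocality are
#' Bernoulli conditional on status; the number of metastatic nodes is 0 for
#' node-negative patients and 1 + negative-binomial (matching the configured
#' mean and SD) for node-positive patients. Clinical covariates carry the
#' emulated conditional shifts (younger, more often premenopausal and
#' symptomatically detected node-positive patients; higher grade; marker
#' shifts), the St Gallen surrogate subtype is derived from the ER/PgR/HER2/
#' Ki67 markers, and per-variable MCAR missingness is applied (categorical
#' missingness is the level `"missing"`, continuous is `NA`). The hidden
#' columns `latent_lvi` and `lesion_*` carry the simulator's ground truth
#' used by the image renderer (LVI before missingness; lesion placement).
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with one row per patient.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n < 1) stop("n_patients must be >= 1")
  local_rng(config$seed)
  # with null_associations everything but LNM comes from pooled marginals
  pick <- function(pos, neg, pooled) {
    if (config$null_associations) list(pos = pooled, neg = pooled)
    else list(pos = pos, neg = neg)
  }
  lnm <- stats::rbinom(n, 1, config$prevalence_lnm)
  bygrp <- function(p) ifelse(lnm == 1, p$pos, p$neg)
  p_ts <- pick(config$size_mean_pos, config$size_mean_neg, 15.6)
  tsize <- rnorm_trunc(n, bygrp(p_ts), config$size_sd, 0, 50)
  lvi <- stats::rbinom(n, 1, bygrp(pick(config$lvi_rate_pos,
                                        config$lvi_rate_neg, 0.17)))
  multifoc <- stats::rbinom(n, 1, bygrp(pick(config$multifoc_rate_pos,
                                             config$multifoc_rate_neg, 0.24)))
  # 1 + NB: match mean m and sd s of the total count among positives
  m_extra <- config$nlnm_mean_pos - 1
  v_extra <- config$nlnm_sd_pos^2
  n_lnm <- integer(n)
  if (any(lnm == 1) && m_extra > 0) {
    size <- if (v_extra > m_extra) m_extra^2 / (v_extra - m_extra) else Inf
    extra <- if (is.finite(size)) {
      stats::rnbinom(sum(lnm == 1), size = size, mu = m_extra)
    } else stats::rpois(sum(lnm == 1), m_extra)
    n_lnm[lnm == 1] <- 1L + extra
  } else n_lnm[lnm == 1] <- 1L
  age <- round(clamp(stats::rnorm(n, bygrp(pick(60.9, 63.7, 62.8)),
                                  bygrp(pick(12.5, 11.3, 11.7))), 25, 95), 1)
  bmi <- round(clamp(stats::rnorm(n, bygrp(pick(26.3, 26.6, 26.5)),
                                  bygrp(pick(5.1, 4.7, 4.8))), 15, 55), 1)
  menop <- ifelse(stats::rbinom(n, 1, bygrp(pick(0.25, 0.15, 0.18))) == 1,
                  "pre", "post")
  detect <- ifelse(stats::rbinom(n, 1, bygrp(pick(0.52, 0.34, 0.39))) == 1,
                   "symptomatic", "mammographic")
  p_gr <- pick(c(0.20, 0.48, 0.32), c(0.27, 0.48, 0.25), c(0.25, 0.48, 0.27))
  grade <- character(n)
  grade[lnm == 1] <- rcat(sum(lnm == 1), c("I", "II", "III"), p_gr$pos)
  grade[lnm == 0] <- rcat(sum(lnm == 0), c("I", "II", "III"), p_gr$neg)
  p_hi <- pick(c(0.82, 0.12, 0.06), c(0.77, 0.13, 0.10), c(0.78, 0.13, 0.09))
  histo <- character(n)
  histo[lnm == 1] <- rcat(sum(lnm == 1), c("NST", "ILC", "other"), p_hi$pos)
  histo[lnm == 0] <- rcat(sum(lnm == 0), c("NST", "ILC", "other"), p_hi$neg)
  er <- ifelse(stats::rbinom(n, 1, bygrp(pick(0.95, 0.91, 0.92))) == 1,
               "pos", "neg")
  pgr <- ifelse(stats::rbinom(n, 1, bygrp(pick(0.89, 0.83, 0.85))) == 1,
                "pos", "neg")
  her2 <- ifelse(stats::rbinom(n, 1, bygrp(pick(0.12, 0.10, 0.10))) == 1,
                 "pos", "neg")
  ki67 <- ifelse(stats::rbinom(n, 1, bygrp(pick(0.52, 0.45, 0.47))) == 1,
                 "pos", "neg")
  subtype <- ifelse(her2 == "pos", "HER2+",
             ifelse(er == "neg" & pgr == "neg", "TNBC",
             ifelse(ki67 == "pos", "LumB", "LumA")))
  # lesion placement inside the breast half-ellipse, shared across views
  les_u <- stats::runif(n, 0.15, 0.60)   # radial fraction
  les_th <- stats::runif(n, -0.9, 0.9)   # angular position (radians)
  les_or <- stats::runif(n, 0, pi)       # lesion orientation
  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, bmi = bmi, menopausal = menop, detection_mode = detect,
    grade = grade, histotype = histo, er = er, pgr = pgr, her2 = her2,
    ki67 = ki67, subtype = subtype,
    outcome_lnm = lnm, outcome_n_lnm = n_lnm, outcome_lvi = lvi,
    outcome_tsize = round(tsize, 1), outcome_multifoc = multifoc,
    latent_lvi = lvi, lesion_u = les_u, lesion_theta = les_th,
    lesion_orient = les_or,
    stringsAsFactors = FALSE)
  # MCAR missingness: categorical -> "missing" level, continuous -> NA;
  # subtype is missing whenever any of its defining markers is missing
  mr <- config$missing_rates
  cat_pred <- c("menopausal", "detection_mode", "grade", "histotype",
                "er", "pgr", "her2", "ki67")
  for (v in names(mr)) {
    if (mr[[v]] <= 0) next
    hit <- stats::runif(n) < mr[[v]]
    if (v %in% cat_pred) cohort[[v]][hit] <- "missing"
    else cohort[[v]][hit] <- NA
  }
  marker_missing <- cohort$er == "missing" | cohort$pgr == "missing" |
    cohort$her2 == "missing" | cohort$ki67 == "missing"
  cohort$subtype[marker_missing] <- "missing"
  stopifnot(all((cohort$outcome_lnm == 0) == (cohort$outcome_n_lnm == 0)))
  cohort
}

# breast half-ellipse geometry shared by renderer and ground-truth mask:
# chest wall on the left edge (column 0), semi-axes a (across) and b (down)
breast_geometry <- function(h, w) {
  list(cx = 0, cy = (h - 1) / 2, a = 0.80 * w, b = 0.46 * h)
}

breast_mask_matrix <- function(h, w, dx = 0, dy = 0) {
  g <- breast_geometry(h, w)
  x <- matrix(rep(0:(w - 1), each = h), h, w) - g$cx - dx
  y <- matrix(rep(0:(h - 1), w), h, w) - g$cy - dy
  (x / g$a)^2 + (y / g$b)^2 <= 1 & x >= 0
}

#' Render one phantom mammogram view
#'
#' Produces a grayscale image (numeric matrix in `[0, 1]`, row = y) with a
#' breast-shaped half-ellipse on a dark background, smooth low-frequency
#' parenchymal texture, one bright elliptical lesion per focus with major
#' axis `outcome_tsize * px_per_mm` pixels (satellite foci when multifocal,
#' each smaller than the index lesion), and a radial spiculation halo
#' around the index lesion whose amplitude grows with LNM and LVI status
#' scaled by `peritumoral_signal_strength`, extending well beyond a
#' tumor-ROI crop. Per-view rotation/translation jitter is deterministic in
#' `(patient_id, view_index, seed)`.
#'
#' @param record One cohort row (as from [generate_cohort()]).
#' @param view_index 0-based view index, `< views_per_patient`.
#' @param config The [cohort_config()] used to generate the cohort.
#' @param seed Cohort-level seed (defaults to `config$seed`).
#' @return A list with `image` (h x w matrix in `[0, 1]`), `annotation`
#'   (`data.frame` with `image_id`, `center_x`, `center_y`; 0-based, x =
#'   column), and `mask` (logical breast-footprint matrix).
#' @export
render_mammogram <- function(record, view_index, config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (view_index < 0 || view_index >= config$views_per_patient)
    stop("view_index out of range")
  h <- config$image_height; w <- config$image_width
  ppm <- config$px_per_mm
  les_d <- record$outcome_tsize * ppm          # major axis in px
  if (les_d > min(h, w)) stop("lesion exceeds image dimensions")
  local_rng(string_seed(record$patient_id, view_index, seed))
  # per-view geometric jitter
  dx <- stats::runif(1, -4, 4); dy <- stats::runif(1, -6, 6)
  rot <- stats::runif(1, -0.06, 0.06)
  g <- breast_geometry(h, w)
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), w), h, w)
  mask <- breast_mask_matrix(h, w, dx, dy)
  img <- matrix(0, h, w)
  # parenchymal texture: a few low-frequency cosine waves
  tex <- matrix(0, h, w)
  for (k in 1:5) {
    fx <- stats::runif(1, 0.3, 1.6) / w
    fy <- stats::runif(1, 0.3, 1.6) / h
    ph <- stats::runif(1, 0, 2 * pi)
    tex <- tex + stats::runif(1, 0.4, 1) *
      cos(2 * pi * (fx * xg + fy * yg) + ph)
  }
  tex <- 0.06 * tex / 5
  img <- (0.28 + tex) * mask
  # index lesion center from the patient's polar placement, jittered
  th <- record$lesion_theta + rot
  r_u <- record$lesion_u
  lcx <- g$cx + dx + r_u * g$a * cos(th)
  lcy <- g$cy + dy + r_u * g$b * sin(th)
  lcx <- clamp(lcx, les_d / 2 + 1, w - les_d / 2 - 2)
  lcy <- clamp(lcy, les_d / 2 + 1, h - les_d / 2 - 2)
  draw_lesion <- function(img, cx, cy, dmaj, orient, amp) {
    ca <- cos(orient); sa <- sin(orient)
    xr <- (xg - cx) * ca + (yg - cy) * sa
    yr <- -(xg - cx) * sa + (yg - cy) * ca
    rho2 <- (xr / (dmaj / 2))^2 + (yr / (0.7 * dmaj / 2))^2
    img + amp * exp(-rho2^2)
  }
  img <- draw_lesion(img, lcx, lcy, les_d, record$lesion_orient, 0.45)
  foci <- list(c(lcx, lcy, les_d))
  if (isTRUE(record$outcome_multifoc == 1)) {
    n_extra <- 1 + stats::rbinom(1, 1, 0.4)
    for (k in seq_len(n_extra)) {
      sd_frac <- stats::runif(1, 0.4, 0.65)
      ang <- stats::runif(1, 0, 2 * pi)
      dist <- les_d * stats::runif(1, 1.2, 2.0) + 8
      scx <- clamp(lcx + dist * cos(ang), 2, w - 3)
      scy <- clamp(lcy + dist * sin(ang), 2, h - 3)
      img <- draw_lesion(img, scx, scy, sd_frac * les_d,
                         stats::runif(1, 0, pi), 0.40)
      foci[[length(foci) + 1]] <- c(scx, scy, sd_frac * les_d)
    }
  }
  # peritumoral spiculation halo around the index lesion
  lnm1 <- isTRUE(record$outcome_lnm == 1)
  lvi1 <- isTRUE((record$latent_lvi %||% record$outcome_lvi) == 1)
  amp <- config$peritumoral_signal_strength * (0.10 * lnm1 + 0.07 * lvi1)
  if (amp > 0) {
    r <- sqrt((xg - lcx)^2 + (yg - lcy)^2)
    r_in <- les_d / 2 + config$halo_inner_mm * ppm
    r_out <- r_in + config$halo_width_mm * ppm
    band <- as.numeric(r >= r_in & r <= r_out) *
      exp(-((r - (r_in + r_out) / 2) / ((r_out - r_in) / 2.2))^2)
    theta <- atan2(yg - lcy, xg - lcx)
    spokes <- 0.55 + 0.45 * cos(12 * theta + stats::runif(1, 0, 2 * pi))
    img <- img + amp * band * spokes
  }
  img <- clamp(img, 0, 1) * mask
  list(image = img,
       annotation = data.frame(
         image_id = sprintf("%s_v%d", record$patient_id, view_index),
         center_x = round(lcx), center_y = round(lcy),
         stringsAsFactors = FALSE),
       mask = mask)
}

#' Render all views of a cohort subset
#'
#' @param cohort Cohort `data.frame`.
#' @param config The matching [cohort_config()].
#' @param patients Optional vector of patient ids to render (default all).
#' @return A list with `images` (named list of matrices keyed by image id),
#'   `annotations` and `manifest` data frames.
#' @export
render_cohort_images <- function(cohort, config, patients = NULL) {
  if (!is.null(patients)) cohort <- cohort[cohort$patient_id %in% patients, ]
  imgs <- list(); ann <- list(); man <- list()
  for (i in seq_len(nrow(cohort))) {
    for (v in 0:(config$views_per_patient - 1)) {
      r <- render_mammogram(cohort[i, ], v, config)
      id <- r$annotation$image_id
      imgs[[id]] <- r$image
      ann[[id]] <- r$annotation
      man[[id]] <- data.frame(image_id = id,
                              patient_id = cohort$patient_id[i],
                              view = v, stringsAsFactors = FALSE)
    }
  }
  list(images = imgs,
       annotations = do.call(rbind, ann),
       manifest = do.call(rbind, man))
}

#' Validate a generated cohort against its configuration
#'
#' Recomputes the univariable effect-size structure on the synthetic table
#' (and optionally a planted-signal check on images) and flags deviations:
#' empirical prevalence against the configured binomial tolerance, the
#' tumor-size Cohen's d and the LVI/multifocality associations against the
#' configured conditional rates, and the outcome-coupling invariant.
#'
#' @param cohort Cohort `data.frame`.
#' @param config The matching [cohort_config()].
#' @param images Optional image list from [render_cohort_images()] to check
#'   annotation bounds.
#' @param conf Confidence level for the binomial prevalence check.
#' @return A list with `checks` (`data.frame` of name/value/ok) and
#'   `table` (the [univariable_table()] report).
#' @export
validate_cohort <- function(cohort, config, images = NULL, conf = 0.99) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("empty cohort")
  n <- nrow(cohort)
  prev <- mean(cohort$outcome_lnm)
  qs <- stats::qbinom(c((1 - conf) / 2, 1 - (1 - conf) / 2), n,
                      config$prevalence_lnm) / n
  tab <- univariable_table(cohort)
  dd <- cohens_d(cohort$outcome_tsize[cohort$outcome_lnm == 1],
                 cohort$outcome_tsize[cohort$outcome_lnm == 0])
  v_mf <- tab$effect[tab$variable == "outcome_multifoc"]
  coupling <- all((cohort$outcome_lnm == 0) == (cohort$outcome_n_lnm == 0))
  checks <- data.frame(
    check = c("prevalence_in_binomial_band", "tsize_d_positive",
              "multifoc_v_positive_assoc", "n_lnm_coupling"),
    value = c(prev, dd, v_mf, as.numeric(coupling)),
    ok = c(prev >= qs[1] & prev <= qs[2], dd > 0, v_mf > 0, coupling),
    stringsAsFactors = FALSE)
  if (!is.null(images)) {
    ann <- images$annotations
    inb <- all(ann$center_x >= 0 & ann$center_x < config$image_width &
               ann$center_y >= 0 & ann$center_y < config$image_height)
    checks <- rbind(checks, data.frame(check = "annotations_in_bounds",
                                       value = as.numeric(inb), ok = inb))
  }
  list(checks = checks, table = tab)
}

#' Write a cohort to disk in the exchange layout
#'
#' `clinical.csv` (one row per patient), 16-bit grayscale PNGs named
#' `{patient_id}_v{view}.png`, `roi.csv` (image_id, center_x, center_y;
#' 0-based) and `manifest.csv` (image_id, patient_id, view).
#'
#' @param cohort Cohort `data.frame`.
#' @param config Matching [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param patients Optional subset of patient ids whose images are written.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir, patients = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort, file.path(dir, "clinical.csv"), row.names = FALSE)
  rc <- render_cohort_images(cohort, config, patients)
  for (id in names(rc$images)) {
    write_png16(rc$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  utils::write.csv(rc$annotations, file.path(dir, "roi.csv"), row.names = FALSE)
  utils::write.csv(rc$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `clinical.csv`, `roi.csv`, `manifest.csv`
#'   and the PNG images.
#' @return A list with `cohort`, `images` (row-major matrices in `[0, 1]`),
#'   `annotations`, `manifest`.
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "clinical.csv"),
                            stringsAsFactors = FALSE)
  ann <- utils::read.csv(file.path(dir, "roi.csv"), stringsAsFactors = FALSE)
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  imgs <- list()
  for (id in man$image_id) {
    p <- file.path(dir, paste0(id, ".png"))
    if (file.exists(p)) imgs[[id]] <- t(EBImage::imageData(EBImage::readImage(p)))
  }
  list(cohort = cohort, images = imgs, annotations = ann, manifest = man)
}
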