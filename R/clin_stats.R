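#' Univariable effect-size statistics for clinical cohorts
#'
#' Tools for the univariable comparison of clinical variables between
#' node-negative and node-positive patients: Welch's t-test and Pearson's
#' chi-square test for significance, Cohen's d and a degrees-of-freedom-scaled
#' Cramer's V for effect size, plus the nontriviality thresholds used to read
#' them (|d| >= 0.50; |V| >= 0.30, 0.21, 0.17 at 1, 2, 3 degrees of freedom).
#'
#' @name clin_stats
NULL

validate_contingency <- function(tab) {
  if (!is.matrix(tab) || !is.numeric(tab))
    stop("contingency table must be a numeric matrix")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2x2")
  if (sum(tab) <= 0)
    stop("contingency table is empty")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an all-zero row or column")
  invisible(tab)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors (at least two finite values each).
#' @return A list with `statistic` (t), `p_value`, and `df`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p_value = 1, df = NA_real_))
    stop("zero variance in both groups")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       p_value   = ht$p.value,
       df        = unname(ht$parameter))
}

#' Pearson's chi-square test of independence
#'
#' Without continuity correction (the correction is never applied, also for
#' 2x2 tables), df = (r-1)(c-1).
#'
#' @param tab An r x c matrix of non-negative integer counts.
#' @return A list with `statistic` (chi-square), `p_value`, and `df`.
#' @examples
#' chi_square_test(rbind(c(695, 288), c(80, 38)))
#' @export
chi_square_test <- function(tab) {
  validate_contingency(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected count of zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic),
       p_value   = ht$p.value,
       df        = unname(ht$parameter))
}

#' Cohen's d standardized mean difference
#'
#' Difference in means divided by a standard deviation. The default pools the
#' two group variances with (n-1) weights; `sd = "whole"` uses the standard
#' deviation of the concatenated sample instead (both conventions occur in the
#' clinical literature; tumor-size effect sizes in development cohorts are
#' often closer to the whole-sample convention).
#'
#' @param x,y Numeric vectors; d > 0 when `mean(x) > mean(y)`.
#' @param sd Either `"pooled"` (default) or `"whole"`.
#' @return Cohen's d (signed).
#' @examples
#' cohens_d(c(2, 3, 4), c(1, 2, 3))   # exactly 1
#' @export
cohens_d <- function(x, y, sd = c("pooled", "whole")) {
  sd <- match.arg(sd)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least two finite values")
  s <- if (sd == "pooled") {
    sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  } else {
    stats::sd(c(x, y))
  }
  if (s == 0) stop("zero standard deviation")
  (mean(x) - mean(y)) / s
}

#' Degrees-of-freedom-scaled Cramer's V
#'
#' Effect size for an r x c contingency table, `V = sqrt(chisq / (n * df))`
#' with `df = (r-1)(c-1)`. For 2x2 tables this equals the classical Cramer's
#' V; for larger tables it is scaled by df rather than `min(r-1, c-1)`, which
#' pairs with the df-dependent nontriviality thresholds (0.30, 0.21, 0.17 for
#' df 1, 2, 3).
#'
#' @param tab An r x c matrix of non-negative integer counts.
#' @return A list with `V`, `df`, plus the underlying `statistic` and
#'   `p_value` of the uncorrected chi-square test.
#' @examples
#' cramers_v(rbind(c(277, 180), c(537, 168)))$V   # ~0.166
#' @export
cramers_v <- function(tab) {
  ct <- chi_square_test(tab)
  n <- sum(tab)
  V <- sqrt(ct$statistic / (n * ct$df))
  list(V = V, df = ct$df, statistic = ct$statistic, p_value = ct$p_value)
}

#' Nontriviality threshold for an effect size
#'
#' @param effect Signed effect size (d or V).
#' @param type `"d"` for continuous variables, `"V"` for categorical.
#' @param df Contingency-table degrees of freedom (required for `"V"`).
#' @return Logical: does |effect| reach the nontriviality threshold
#'   (|d| >= 0.50; |V| >= 0.30, 0.21, 0.17 for df = 1, 2, >= 3)?
#' @export
nontrivial_effect <- function(effect, type = c("d", "V"), df = NULL) {
  type <- match.arg(type)
  if (type == "d") return(abs(effect) >= 0.50)
  if (is.null(df)) stop("df required for Cramer's V thresholds")
  thr <- if (df <= 1) 0.30 else if (df == 2) 0.21 else 0.17
  abs(effect) >= thr
}

# variable roles used by univariable_table()
.uni_continuous <- c("age", "bmi", "outcome_tsize", "outcome_n_lnm")
.uni_categorical <- c("menopausal", "detection_mode", "histotype", "grade",
                      "er", "pgr", "her2", "ki67", "subtype",
                      "outcome_multifoc", "outcome_lvi")

#' Univariable comparison of a cohort by nodal status
#'
#' Runs, per variable, Welch's t-test + Cohen's d (continuous) or the
#' uncorrected chi-square test + df-scaled Cramer's V (categorical), comparing
#' node-positive against node-negative patients. Missing entries (NA or the
#' literal level `"missing"`) are excluded variable-wise (complete-case per
#' row of the report), and the nontriviality flag is applied per the
#' df-dependent thresholds.
#'
#' @param cohort A cohort `data.frame` as returned by [generate_cohort()]
#'   (needs an `outcome_lnm` column in 0/1 coding).
#' @param variables Which columns to test; defaults to the standard predictor
#'   and outcome set present in the cohort.
#' @return A `data.frame` with one row per variable: `variable`, `type`,
#'   `n_used`, `n_missing`, `statistic`, `df`, `p_value`, `effect`,
#'   `nontrivial`.
#' @export
univariable_table <- function(cohort, variables = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("empty cohort")
  if (!"outcome_lnm" %in% names(cohort)) stop("cohort lacks outcome_lnm")
  grp <- cohort$outcome_lnm
  if (length(unique(grp)) < 2L) stop("both nodal classes required")
  if (is.null(variables))
    variables <- intersect(c(.uni_continuous, .uni_categorical), names(cohort))
  rows <- lapply(variables, function(v) {
    val <- cohort[[v]]
    miss <- is.na(val) | (is.character(val) | is.factor(val)) &
      as.character(val) == "missing"
    use <- !miss
    n_used <- sum(use)
    if (v %in% .uni_continuous) {
      x <- as.numeric(val[use & grp == 1]); y <- as.numeric(val[use & grp == 0])
      ht <- welch_t_test(x, y)
      eff <- cohens_d(x, y)
      data.frame(variable = v, type = "continuous", n_used = n_used,
                 n_missing = sum(miss), statistic = ht$statistic,
                 df = ht$df, p_value = ht$p_value, effect = eff,
                 nontrivial = nontrivial_effect(eff, "d"),
                 stringsAsFactors = FALSE)
    } else {
      f <- factor(as.character(val[use]))
      if (nlevels(f) < 2L) stop("variable '", v, "' has <2 observed levels")
      tab <- unclass(table(f, grp[use]))  # rows = levels, cols = nodal status
      dimnames(tab) <- NULL
      tab <- matrix(as.numeric(tab), nrow = nlevels(f))
      cv <- cramers_v(tab)
      data.frame(variable = v, type = "categorical", n_used = n_used,
                 n_missing = sum(miss), statistic = cv$statistic,
                 df = cv$df, p_value = cv$p_value, effect = cv$V,
                 nontrivial = nontrivial_effect(cv$V, "V", cv$df),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Published univariable contingency counts of a breast-cancer cohort
#'
#' Contingency tables (variable level x nodal status) for the clinical
#' variables of a published supervised-learning cohort of 1162 women with
#' early invasive breast cancer (814 node-negative, 348 node-positive),
#' transcribed from the printed patient-characteristics table. Rows are
#' variable levels, columns are `node_neg` and `node_pos`; missing entries
#' are excluded (complete-case per variable). Used to validate the
#' effect-size implementations against the printed values.
#'
#' @return A named list of integer matrices.
#' @examples
#' round(cramers_v(reference_cohort_counts()$lvi)$V, 3)   # 0.264
#' @export
reference_cohort_counts <- function() {
  m <- function(x, rn) matrix(x, ncol = 2, byrow = TRUE,
                              dimnames = list(rn, c("node_neg", "node_pos")))
  list(
    detection_mode = m(c(277, 180, 537, 168), c("symptomatic", "mammographic")),
    menopausal     = m(c(660, 250, 118, 83), c("post", "pre")),
    multifocality  = m(c(656, 230, 158, 118), c("no", "yes")),
    lvi            = m(c(651, 194, 78, 94), c("negative", "positive")),
    grade          = m(c(216, 71, 385, 166, 202, 110), c("I", "II", "III")),
    histotype      = m(c(623, 285, 107, 43, 84, 20), c("NST", "ILC", "other")),
    subtype        = m(c(462, 177, 165, 96, 80, 38, 56, 11),
                       c("LumA", "LumB", "HER2+", "TNBC")),
    her2           = m(c(695, 288, 80, 38), c("negative", "positive")),
    er             = m(c(72, 17, 738, 331), c("negative", "positive")),
    pgr            = m(c(140, 39, 670, 309), c("negative", "positive")),
    ki67           = m(c(435, 160, 350, 175), c("negative", "positive"))
  )
}
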