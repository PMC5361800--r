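#' Body surface area
#'
#' Mosteller formula (default): `sqrt(height * weight / 3600)`; DuBois
#' optional: `0.007184 * height^0.725 * weight^0.425`.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @param formula `"mosteller"` or `"dubois"`.
#' @return BSA in m^2.
#' @export
compute_bsa <- function(height_cm, weight_kg,
                        formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  switch(formula,
    mosteller = sqrt(height_cm * weight_kg / 3600),
    dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425)
}

#' Define a normative diameter model
#'
#' Normative mean and SD of a vessel diameter as low-order polynomials of a
#' body-size predictor (BSA, height or age), used for Z-score computation.
#' The polynomial coefficients are supplied in increasing order (intercept
#' first). Shipped example models are synthetic illustrations, not published
#' regressions.
#'
#' @param site measurement site label (e.g. "sinus", "proximal_DAo").
#' @param predictor `"BSA"`, `"height"` or `"age"`.
#' @param mean_coef polynomial coefficients of the normative mean (mm).
#' @param sd_coef polynomial coefficients of the normative SD (mm); the SD
#'   must be positive over `range`.
#' @param range valid predictor range `c(lo, hi)`.
#' @param source free-text provenance label.
#' @return object of class `normative_model`.
#' @export
normative_model <- function(site, predictor = c("BSA", "height", "age"),
                            mean_coef, sd_coef, range, source = "synthetic") {
  predictor <- match.arg(predictor)
  stopifnot(length(range) == 2L, range[1] < range[2])
  pv <- function(coef, x) {
    drop(outer(x, seq_along(coef) - 1, `^`) %*% coef)
  }
  chk <- seq(range[1], range[2], length.out = 50)
  if (any(pv(sd_coef, chk) <= 0)) {
    stop("normative SD must be positive over the declared predictor range")
  }
  structure(list(site = site, predictor = predictor, mean_coef = mean_coef,
                 sd_coef = sd_coef, range = range, source = source),
            class = "normative_model")
}

#' Load normative models from a JSON file
#'
#' Reads a JSON file with a `models` array of [normative_model()] argument
#' sets. The file shipped under `extdata/normative_models_synthetic.json` is
#' a synthetic illustration (linear mean, constant SD in BSA), not a
#' published regression.
#'
#' @param path JSON file; defaults to the shipped synthetic example.
#' @return named list of `normative_model` objects (by site).
#' @export
load_normative_models <- function(path = system.file(
  "extdata", "normative_models_synthetic.json", package = "aorta4d")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(x$models)), function(i) {
    m <- x$models[i, ]
    normative_model(m$site, m$predictor, unlist(m$mean_coef),
                    unlist(m$sd_coef), unlist(m$range), m$source)
  })
  names(out) <- x$models$site
  out
}

#' Diameter Z-score
#'
#' `z = (diameter - normative mean(predictor)) / normative SD(predictor)`.
#' A Z-score above 2 conventionally defines dilatation.
#'
#' @param diameter_mm measured diameter, mm.
#' @param predictor_value body-size predictor value (must lie in the model's
#'   declared range).
#' @param model a [normative_model()].
#' @return Z-score (numeric), with attribute `dilated` (`z > 2`).
#' @export
zscore <- function(diameter_mm, predictor_value, model) {
  stopifnot(inherits(model, "normative_model"))
  if (any(predictor_value < model$range[1] | predictor_value > model$range[2])) {
    stop("predictor outside the model's valid range [",
         model$range[1], ", ", model$range[2], "]")
  }
  pv <- function(coef, x) drop(outer(x, seq_along(coef) - 1, `^`) %*% coef)
  z <- (diameter_mm - pv(model$mean_coef, predictor_value)) /
    pv(model$sd_coef, predictor_value)
  attr(z, "dilated") <- z > 2
  z
}

# one-sample Kolmogorov-Smirnov normality check with estimated parameters
ks_normal_p <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value)
}

#' Normality-gated paired comparison
#'
#' Checks normality of the paired differences with a Kolmogorov-Smirnov
#' test (alpha = 0.05); a normal result selects the two-sided paired t-test,
#' otherwise the Wilcoxon signed-rank test. Identical vectors return p = 1
#' with a warning (degenerate case).
#'
#' @param x1,x2 paired measurements, equal length, n >= 3.
#' @return list: `test`, `statistic`, `p_value`, `n`, `normality_p`.
#' @export
compare_paired <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 3L)
  d <- x2 - x1
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(test = "degenerate", statistic = NA_real_, p_value = 1,
                n = length(d), normality_p = NA_real_))
  }
  if (stats::sd(d) == 0) {
    warning("paired differences are a non-zero constant (zero variance)")
    return(list(test = "degenerate", statistic = NA_real_, p_value = 0,
                n = length(d), normality_p = NA_real_))
  }
  pn <- ks_normal_p(d)
  if (pn >= 0.05) {
    ht <- stats::t.test(x2, x1, paired = TRUE)
    list(test = "paired_t", statistic = unname(ht$statistic),
         p_value = ht$p.value, n = length(d), normality_p = pn)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x2, x1, paired = TRUE,
                                              exact = FALSE))
    list(test = "wilcoxon_signed_rank", statistic = unname(ht$statistic),
         p_value = ht$p.value, n = length(d), normality_p = pn)
  }
}

#' Normality-gated two-group comparison
#'
#' Kolmogorov-Smirnov normality check on each group (alpha = 0.05); if both
#' pass, a two-sided two-sample Student t-test (pooled variance; Welch via
#' `welch = TRUE`), otherwise the Mann-Whitney U test.
#'
#' @param x,y group measurements, n >= 3 each.
#' @param welch use the Welch instead of the pooled-variance t-test.
#' @return list: `test`, `statistic`, `p_value`, `n`, `normality_p`.
#' @export
compare_groups <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  if (stats::sd(c(x, y)) == 0) {
    warning("both groups are the same constant; p = 1")
    return(list(test = "degenerate", statistic = NA_real_, p_value = 1,
                n = c(length(x), length(y)), normality_p = NA_real_))
  }
  pn <- min(ks_normal_p(x), ks_normal_p(y))
  if (pn >= 0.05) {
    ht <- stats::t.test(x, y, var.equal = !welch)
    list(test = if (welch) "welch_t" else "student_t",
         statistic = unname(ht$statistic), p_value = ht$p.value,
         n = c(length(x), length(y)), normality_p = pn)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(test = "mann_whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value, n = c(length(x), length(y)), normality_p = pn)
  }
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return list: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the marginal rating
#' distributions.
#'
#' @param r1,r2 equal-length categorical rating vectors.
#' @return kappa (numeric scalar).
#' @export
cohens_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) > 0L)
  lev <- sort(unique(c(r1, r2)))
  if (length(lev) < 2L) {
    stop("kappa undefined: ratings use a single shared category")
  }
  tab <- table(factor(r1, levels = lev), factor(r2, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < 1e-12) stop("kappa undefined: expected agreement is 1")
  (po - pe) / (1 - pe)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and 95% limits of agreement
#' `bias +/- 1.96 * sd(differences)`, plus each value as a percentage of the
#' grand mean of all measurements.
#'
#' @param m1,m2 paired measurements from the two observers/methods, n >= 3.
#' @return list: `bias`, `lower`, `upper`, `sd_diff`, `mean_value`, and
#'   `percent_of_mean` (named: bias, lower, upper).
#' @export
bland_altman <- function(m1, m2) {
  stopifnot(length(m1) == length(m2), length(m1) >= 3L)
  d <- m1 - m2
  bias <- mean(d)
  s <- stats::sd(d)
  lower <- bias - 1.96 * s
  upper <- bias + 1.96 * s
  gm <- mean(c(m1, m2))
  pct <- if (abs(gm) > 1e-12) {
    100 * abs(c(bias = bias, lower = lower, upper = upper)) / abs(gm)
  } else c(bias = NA_real_, lower = NA_real_, upper = NA_real_)
  list(bias = bias, lower = lower, upper = upper, sd_diff = s,
       mean_value = gm, percent_of_mean = pct)
}
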