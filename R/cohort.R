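#' Read a subject measurement table
#'
#' Expects a CSV with one row per subject and timepoint: columns `id`,
#' `timepoint` (e.g. "t1", "t2", "volunteer"), the demographics
#' `age_years`, `height_cm`, `weight_kg`, and any number of numeric
#' measurement columns (diameters in mm, segmental WSS in N/m^2, peak
#' velocities in m/s, flow grades). A shipped synthetic example is at
#' `system.file("extdata", "subjects_synthetic.csv", package = "aorta4d")`.
#'
#' @param path CSV file.
#' @param bsa_formula formula passed to [compute_bsa()]; a `bsa_m2` column
#'   is added when height and weight are present.
#' @return data.frame of subject records.
#' @export
read_subject_table <- function(path, bsa_formula = "mosteller") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timepoint")
  if (!all(need %in% names(df))) {
    stop("subject table needs columns: ", paste(need, collapse = ", "))
  }
  if (all(c("height_cm", "weight_kg") %in% names(df))) {
    df$bsa_m2 <- compute_bsa(df$height_cm, df$weight_kg, bsa_formula)
  }
  df
}

#' Cohort comparison report
#'
#' Runs the standard statistical battery over a subject table: for every
#' measurement variable, a paired comparison between the two patient
#' timepoints (subjects matched by `id`), unpaired comparisons of each
#' timepoint against the volunteer group, and any requested Pearson
#' correlations. Diameter columns with a matching [normative_model()] gain
#' Z-score columns (`z_<site>`, predictor taken from the subject's BSA).
#' All tests are two-sided at alpha = 0.05 with the normality-gated test
#' choice of [compare_paired()] / [compare_groups()]; no multiple-testing
#' correction is applied (each test is reported at its nominal level).
#'
#' @param subjects data.frame from [read_subject_table()].
#' @param normative optional named list of `normative_model`s; a model
#'   named `site` is applied to column `<site>_mm`.
#' @param variables measurement columns to compare; defaults to all numeric
#'   columns except id/demographics.
#' @param correlations optional list of `c(x, y)` column-name pairs.
#' @param timepoints character vector: the two paired levels followed by
#'   the reference group level.
#' @return object of class `cohort_report`: list with `subjects` (augmented
#'   table), `comparisons` (data.frame: variable, contrast, test, statistic,
#'   p_value, n), and `correlations` (data.frame).
#' @export
cohort_report <- function(subjects, normative = NULL, variables = NULL,
                          correlations = NULL,
                          timepoints = c("t1", "t2", "volunteer")) {
  stopifnot(is.data.frame(subjects))
  if (!is.null(normative)) {
    for (site in names(normative)) {
      col <- paste0(site, "_mm")
      if (col %in% names(subjects) && "bsa_m2" %in% names(subjects)) {
        ok <- !is.na(subjects[[col]]) & !is.na(subjects$bsa_m2)
        z <- rep(NA_real_, nrow(subjects))
        z[ok] <- as.numeric(zscore(subjects[[col]][ok],
                                   subjects$bsa_m2[ok], normative[[site]]))
        subjects[[paste0("z_", site)]] <- z
      }
    }
  }
  if (is.null(variables)) {
    drop <- c("id", "age_years", "height_cm", "weight_kg")
    variables <- setdiff(names(subjects)[vapply(subjects, is.numeric,
                                                logical(1))], drop)
  }
  tp <- timepoints
  comp <- list()
  add <- function(variable, contrast, res) {
    comp[[length(comp) + 1L]] <<- data.frame(
      variable = variable, contrast = contrast, test = res$test,
      statistic = res$statistic, p_value = res$p_value,
      n = paste(res$n, collapse = "/"))
  }
  for (v in variables) {
    d1 <- subjects[subjects$timepoint == tp[1], c("id", v)]
    d2 <- subjects[subjects$timepoint == tp[2], c("id", v)]
    dv <- subjects[subjects$timepoint == tp[3], v]
    dv <- dv[!is.na(dv)]
    both <- merge(d1, d2, by = "id")
    both <- both[stats::complete.cases(both), ]
    if (nrow(both) >= 3L) {
      add(v, paste0(tp[1], "_vs_", tp[2]),
          suppressWarnings(compare_paired(both[[2]], both[[3]])))
    }
    for (k in 1:2) {
      g <- subjects[subjects$timepoint == tp[k], v]
      g <- g[!is.na(g)]
      if (length(g) >= 3L && length(dv) >= 3L) {
        add(v, paste0(tp[k], "_vs_", tp[3]),
            suppressWarnings(compare_groups(g, dv)))
      }
    }
  }
  cors <- NULL
  if (!is.null(correlations)) {
    cors <- do.call(rbind, lapply(correlations, function(pr) {
      do.call(rbind, lapply(tp[1:2], function(t_lev) {
        sub <- subjects[subjects$timepoint == t_lev, pr]
        sub <- sub[stats::complete.cases(sub), ]
        if (nrow(sub) < 3L || stats::sd(sub[[1]]) == 0 ||
            stats::sd(sub[[2]]) == 0) return(NULL)
        pc <- pearson(sub[[1]], sub[[2]])
        data.frame(x = pr[1], y = pr[2], timepoint = t_lev, r = pc$r,
                   p_value = pc$p_value, n = pc$n)
      }))
    }))
  }
  structure(list(subjects = subjects,
                 comparisons = do.call(rbind, comp),
                 correlations = cors),
            class = "cohort_report")
}
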