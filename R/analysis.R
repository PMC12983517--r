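# The study-level statistical stage over a cohort dataset: univariate
# correct-vs-misdiagnosed comparisons, the clustered multivariate GEE,
# mixed-effects learning curves, and M1-vs-M2 start/end contrasts.

TABLE1_VARS <- c(
  "ddx_pct", "dxj_pct", "inv_pct", "error_count",
  "time_history", "time_physical", "time_investigations",
  "views_history", "views_physical", "views_investigations",
  "n_tests", "n_rounds",
  "unused_results_count", "inappropriate_tests_count",
  "excess_tests", "excess_rounds"
)

#' Univariate correct-vs-misdiagnosed comparisons
#'
#' For each analysis variable, compares cases diagnosed correctly against
#' misdiagnosed ones: group means and SDs, the percent difference
#' `(mean_correct - mean_incorrect) / mean_incorrect * 100`, and a two-group
#' test -- a t-test when a Shapiro-Wilk check (on a capped subsample) does
#' not reject normality, a Wilcoxon rank-sum test otherwise, and a
#' two-proportion test for binary variables. Constant variables are skipped
#' with a recorded reason.
#'
#' @param dataset A cohort dataset (see [as_cohort_dataset()]).
#' @param vars Variables to compare; defaults to every score, error, time,
#'   navigation and penalty column present.
#' @param shapiro_alpha Normality rejection level. Default 0.05.
#' @param shapiro_cap Maximum subsample size for the normality check.
#' @return A tibble with one row per variable: group means/SDs, percent
#'   difference, test used, p-value, and a note for skipped variables.
#' @export
compare_groups <- function(dataset, vars = NULL, shapiro_alpha = 0.05,
                           shapiro_cap = 3000) {
  vars <- vars %||% intersect(TABLE1_VARS, names(dataset))
  g1 <- dataset[dataset$correct == TRUE, , drop = FALSE]
  g0 <- dataset[dataset$correct == FALSE, , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g0) < 2) {
    vpdx_abort("compare_groups: need at least 2 cases in each outcome group")
  }
  rows <- lapply(vars, function(v) {
    x1 <- as.numeric(g1[[v]]); x0 <- as.numeric(g0[[v]])
    out <- tibble::tibble(
      variable = v,
      mean_correct = mean(x1), sd_correct = sd(x1),
      mean_incorrect = mean(x0), sd_incorrect = sd(x0),
      pct_difference = if (mean(x0) != 0)
        (mean(x1) - mean(x0)) / mean(x0) * 100 else NA_real_,
      test = NA_character_, p.value = NA_real_, note = NA_character_
    )
    if (sd(c(x1, x0)) == 0) {
      out$test <- "skipped"; out$note <- "constant variable"
      return(out)
    }
    binary <- all(c(x1, x0) %in% c(0, 1))
    if (binary) {
      m <- matrix(c(sum(x1), length(x1) - sum(x1),
                    sum(x0), length(x0) - sum(x0)), nrow = 2, byrow = TRUE)
      out$test <- "prop"
      out$p.value <- suppressWarnings(prop.test(m)$p.value)
      return(out)
    }
    sub <- function(x) if (length(x) > shapiro_cap) x[seq_len(shapiro_cap)] else x
    normal <- tryCatch({
      shapiro.test(sub(x1))$p.value > shapiro_alpha &&
        shapiro.test(sub(x0))$p.value > shapiro_alpha
    }, error = function(e) FALSE)
    if (normal) {
      out$test <- "t"
      out$p.value <- t.test(x1, x0)$p.value
    } else {
      out$test <- "wilcoxon"
      out$p.value <- suppressWarnings(wilcox.test(x1, x0)$p.value)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Multivariate GEE of diagnostic accuracy on reasoning components
#'
#' Fits a marginal logistic model of per-case correctness on the clinical
#' reasoning components, clustered on students with an AR(1) working
#' correlation over the case sequence, with school as a fixed covariate.
#' Component percent scores enter on a 0-10 point scale (percent / 10),
#' time variables are log-transformed, and highly skewed count variables
#' are dichotomized to zero/nonzero before fitting; the transformation log
#' records each decision. Robust standard errors are reported.
#'
#' @param dataset A cohort dataset sorted by (student, sequence).
#' @param predictors Analysis variables to include alongside school.
#'   Defaults to the four reasoning components.
#' @param corstr Working correlation (default `"ar1"`).
#' @param cluster `"student"` (default) or `"school"`.
#' @param school_covariate Include school fixed effects (default `TRUE`).
#' @param skew_cutoff Absolute skewness beyond which a count variable is
#'   dichotomized. Default 2.
#' @param prune_alpha If non-`NULL`, predictors with p-values above this
#'   level are removed one at a time (least significant first) and listed
#'   in `excluded` with reason "Not significant, removed".
#' @return A list of class `vpdx_gee_result`: `fit` (the [gee_logit()]
#'   object), `table` (predictor rows only), `transformations`, `excluded`,
#'   `corstr`, `cluster`.
#' @export
fit_gee <- function(dataset,
                    predictors = c("dxj_pct", "inv_pct", "ddx_pct", "error_count"),
                    corstr = "ar1", cluster = c("student", "school"),
                    school_covariate = TRUE, skew_cutoff = 2,
                    prune_alpha = NULL) {
  cluster <- match.arg(cluster)
  dataset <- dplyr::arrange(dataset, .data$school_id, .data$student_id,
                            .data$sequence_index)
  df <- data.frame(correct = as.numeric(dataset$correct))
  transformations <- list()
  terms <- character()
  for (v in predictors) {
    x <- as.numeric(dataset[[v]])
    nm <- v
    if (grepl("_pct$", v)) {
      x <- x / 10
      nm <- sub("_pct$", "_pts", v)
      transformations[[v]] <- "percent / 10 (0-10 point scale)"
    } else if (grepl("^time_", v)) {
      x <- log(pmax(x, 1 / 60))
      nm <- paste0("log_", v)
      transformations[[v]] <- "log-transformed"
    } else if (!all(x %in% c(0, 1)) &&
               abs(e1071::skewness(x, type = 2)) > skew_cutoff) {
      x <- as.numeric(x > 0)
      nm <- paste0(v, "_any")
      transformations[[v]] <- "dichotomized (zero vs nonzero; highly skewed)"
    } else {
      transformations[[v]] <- "untransformed"
    }
    df[[nm]] <- x
    terms <- c(terms, nm)
  }
  if (school_covariate && length(unique(dataset$school_id)) > 1) {
    df$school_id <- factor(dataset$school_id)
    terms <- c(terms, "school_id")
  }
  id <- if (cluster == "student") dataset$student_id else dataset$school_id
  excluded <- tibble::tibble(term = character(), reason = character())
  repeat {
    form <- as.formula(paste("correct ~", paste(terms, collapse = " + ")))
    fit <- gee_logit(form, df, id = id, corstr = corstr)
    if (is.null(prune_alpha)) break
    tab <- fit$table[!grepl("^\\(Intercept\\)|^school_id", fit$table$term), ]
    worst <- tab[which.max(tab$p.value), ]
    if (nrow(worst) == 0 || worst$p.value <= prune_alpha || length(terms) <= 1) break
    drop_nm <- terms[vapply(terms, function(t) grepl(t, worst$term, fixed = TRUE),
                            logical(1))][1]
    terms <- setdiff(terms, drop_nm)
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      term = drop_nm, reason = "Not significant, removed"))
  }
  structure(list(
    fit = fit,
    table = fit$table[!grepl("^\\(Intercept\\)|^school_id", fit$table$term), ],
    transformations = transformations,
    excluded = excluded,
    corstr = corstr, cluster = cluster,
    working_alpha = fit$alpha
  ), class = "vpdx_gee_result")
}

#' Mixed-effects learning curves across the case sequence
#'
#' Per metric, fits a generalized mixed-effects model with a random student
#' intercept and a fixed trend in the case sequence (`log(t)` by default,
#' matching the steep-then-slowing growth shape): binomial for
#' correctness, gaussian for percent scores, Poisson for the error count.
#' Returns the population-level trend with a 95% confidence band over
#' `sequence_index`.
#'
#' @param dataset A cohort dataset.
#' @param metrics Columns to model.
#' @param shape `"log"` or `"linear"` trend in sequence index.
#' @return A list of class `vpdx_learning_curves`: per metric, the model
#'   family, fixed effects, random-intercept SD, slope p-value and the
#'   trend tibble (`sequence_index`, `fit`, `lwr`, `upr`).
#' @export
fit_learning_curves <- function(dataset,
                                metrics = c("ddx_pct", "dxj_pct", "inv_pct",
                                            "error_count", "correct"),
                                shape = c("log", "linear")) {
  shape <- match.arg(shape)
  ts <- sort(unique(dataset$sequence_index))
  if (length(ts) < 2) vpdx_abort("learning curves need >= 2 sequence positions")
  df <- data.frame(
    student_id = dataset$student_id,
    t = dataset$sequence_index,
    ft = f_learn(dataset$sequence_index, shape)
  )
  out <- lapply(setNames(metrics, metrics), function(mv) {
    y <- dataset[[mv]]
    fam <- if (is.logical(y) || all(y %in% c(0, 1))) "binomial"
           else if (mv == "error_count" ||
                    (all(y >= 0) && all(y == round(y)))) "poisson"
           else "gaussian"
    df$y <- as.numeric(y)
    fit <- tryCatch({
      if (fam == "gaussian") {
        lme4::lmer(y ~ ft + (1 | student_id), data = df, REML = FALSE)
      } else {
        lme4::glmer(y ~ ft + (1 | student_id), data = df,
                    family = if (fam == "binomial") binomial() else poisson(),
                    nAGQ = 0L)
      }
    }, error = function(e) {
      vpdx_abort(paste0("learning-curve fit failed for '", mv, "': ",
                        conditionMessage(e)))
    })
    fe <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    ftg <- f_learn(ts, shape)
    Xg <- cbind(1, ftg)
    lin <- drop(Xg %*% fe)
    se <- sqrt(rowSums((Xg %*% vc) * Xg))
    inv_link <- switch(fam, binomial = plogis, poisson = exp,
                       gaussian = identity)
    slope_se <- sqrt(vc[2, 2])
    slope_p <- 2 * pnorm(-abs(fe[2] / slope_se))
    list(
      metric = mv, family = fam,
      fixed = fe,
      slope_p = unname(slope_p),
      ranef_sd = sqrt(unlist(lme4::VarCorr(fit))[1]),
      trend = tibble::tibble(
        sequence_index = ts,
        fit = inv_link(lin),
        lwr = inv_link(lin - 1.96 * se),
        upr = inv_link(lin + 1.96 * se))
    )
  })
  structure(out, class = "vpdx_learning_curves")
}

#' Start-versus-end cohort contrasts
#'
#' Compares the M1 and M2 cohorts at the start of the curriculum
#' (sequence index 1) and at each cohort's final completed case, on
#' justification, test ordering, misdiagnosis rate and error rate, using
#' the univariate machinery (two-proportion test for rates, t/Wilcoxon for
#' scores).
#'
#' @param dataset A cohort dataset containing both cohorts.
#' @param metrics Metrics to contrast.
#' @return A tibble with one row per (period, metric): cohort means and the
#'   p-value. Degenerate single-case cohorts (start == end) are flagged in
#'   the `note` column.
#' @export
compare_cohorts <- function(dataset,
                            metrics = c("dxj_pct", "inv_pct", "correct",
                                        "error_count")) {
  cohorts <- unique(dataset$cohort)
  if (!all(c("M1", "M2") %in% cohorts)) {
    vpdx_abort("compare_cohorts: dataset must contain both M1 and M2 cohorts")
  }
  ends <- vapply(c("M1", "M2"), function(ch) {
    max(dataset$sequence_index[dataset$cohort == ch])
  }, numeric(1))
  rows <- list()
  for (period in c("start", "end")) {
    sel <- lapply(c(M1 = "M1", M2 = "M2"), function(ch) {
      t_at <- if (period == "start") 1 else ends[[ch]]
      dataset[dataset$cohort == ch & dataset$sequence_index == t_at, ,
              drop = FALSE]
    })
    for (mv in metrics) {
      x1 <- as.numeric(sel$M1[[mv]]); x2 <- as.numeric(sel$M2[[mv]])
      binary <- all(c(x1, x2) %in% c(0, 1))
      p <- if (sd(c(x1, x2)) == 0) NA_real_
      else if (binary) {
        suppressWarnings(prop.test(matrix(c(sum(x1), length(x1) - sum(x1),
                                            sum(x2), length(x2) - sum(x2)),
                                          2, byrow = TRUE))$p.value)
      } else {
        suppressWarnings(wilcox.test(x1, x2)$p.value)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        period = period, metric = mv,
        mean_M1 = mean(x1), mean_M2 = mean(x2), p.value = p,
        note = if (ends[["M2"]] == 1 && period == "end")
          "M2 has a single case: start == end" else NA_character_
      )
    }
  }
  dplyr::bind_rows(rows)
}
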