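# The algorithmic scorecard: component percent scores, final-diagnosis
# credit, penalties and navigation metrics for one trace against one rubric.

# Precompiled lookup structures shared by the scorers and the error
# detectors. `case` supplies free-text lexicons; without it, matching falls
# back to identity lexicons over the rubric's own labels.
prepare_rubric <- function(scorecard, case = NULL, max_edit_distance = 0) {
  if (inherits(scorecard, "vp_rubric")) return(scorecard)
  stopifnot(inherits(scorecard, "vp_scorecard"))
  dx_lex <- if (!is.null(case)) case$diagnosis_lexicon else list()
  for (d in unique(c(scorecard$appropriate_diagnoses, scorecard$correct_diagnosis))) {
    if (is.null(dx_lex[[d]])) dx_lex[[d]] <- character()
  }
  dx_idx <- lexicon_index(dx_lex)

  test_ids <- unique(c(scorecard$test_labels$test_id, scorecard$test_links$test_id))
  test_lex <- setNames(as.list(rep("", length(test_ids))), test_ids)
  test_lex <- lapply(test_lex, function(x) character())
  if (!is.null(case)) {
    for (i in seq_len(nrow(case$tests))) {
      tid <- case$tests$test_id[i]
      test_lex[[tid]] <- unique(c(test_lex[[tid]], case$tests$name[i],
                                  case$tests$synonyms[[i]]))
    }
  }
  test_idx <- lexicon_index(test_lex)

  dl <- scorecard$dxj_labels
  key <- paste(dl$datum_id, dl$diagnosis, sep = "\r")
  lab <- setNames(dl$label, key)
  req <- dl[dl$label %in% c("required_increase", "required_decrease"), , drop = FALSE]
  req_key <- paste(req$datum_id, req$diagnosis, sep = "\r")
  req_dir <- setNames(
    ifelse(req$label == "required_increase", "increases", "decreases"), req_key)

  tl <- scorecard$test_labels
  datum_ids <- unique(c(dl$datum_id, tl$test_id,
                        if (!is.null(case)) case$findings$finding_id,
                        if (!is.null(case)) case$tests$test_id))
  structure(list(
    scorecard = scorecard,
    correct = scorecard$correct_diagnosis,
    appropriate = scorecard$appropriate_diagnoses,
    dx_idx = dx_idx,
    test_idx = test_idx,
    med = max_edit_distance,
    label_map = lab,
    req_dir = req_dir,
    req_df = req,
    required_tests = tl$test_id[tl$label == "required"],
    inappropriate_tests = tl$test_id[tl$label == "inappropriate"],
    test_links = scorecard$test_links,
    datum_ids = datum_ids,
    finding_stage = if (!is.null(case))
      setNames(case$findings$stage, case$findings$finding_id) else NULL
  ), class = "vp_rubric")
}

# canonicalized view of the trace against a rubric; computed once per case
resolve_trace <- function(trace, rubric) {
  da <- trace$dxj_assignments
  dx_canon <- if (nrow(da)) match_free_text(da$diagnosis, rubric$dx_idx, rubric$med)
              else character()
  if (nrow(da)) {
    unknown <- setdiff(unique(da$datum_id), rubric$datum_ids)
    if (length(unknown)) {
      vpdx_abort(paste0("dxj_assignments: unknown datum_id '", unknown[1], "'"))
    }
  }
  ordered_raw <- trace$test_orders$test_text
  ordered_canon <- if (length(ordered_raw))
    match_free_text(ordered_raw, rubric$test_idx, rubric$med) else character()
  snaps <- lapply(trace$ddx_snapshots, function(s) {
    ent <- if (length(s$entries)) match_free_text(s$entries, rubric$dx_idx, rubric$med)
           else character()
    list(stage = s$stage, entries = ent,
         raw_entries = s$entries,
         most_probable = if (length(ent)) ent[[1]] else NA_character_)
  })
  final_canon <- if (nzchar(trace$final_diagnosis %||% ""))
    match_free_text(trace$final_diagnosis, rubric$dx_idx, rubric$med)
    else NA_character_
  # deduplicated assignment keys actually made, with direction
  akey <- if (nrow(da)) paste(da$datum_id, dx_canon, sep = "\r") else character()
  keep <- if (nrow(da)) !is.na(dx_canon) & !duplicated(paste(akey, da$direction))
          else logical()
  list(
    assignments = data.frame(
      datum_id = da$datum_id[keep], diagnosis = dx_canon[keep],
      direction = da$direction[keep], key = akey[keep],
      stringsAsFactors = FALSE),
    unmatched_dx = if (nrow(da)) unique(da$diagnosis[is.na(dx_canon)]) else character(),
    ordered_tests = unique(ordered_canon[!is.na(ordered_canon)]),
    unmatched_tests = unique(ordered_raw[is.na(ordered_canon)]),
    n_test_orders = nrow(trace$test_orders),
    n_rounds = length(unique(trace$test_orders$round_index)),
    snapshots = snaps,
    final = final_canon
  )
}

#' Score the differential diagnosis component
#'
#' A learner earns one point for each rubric-appropriate diagnosis that
#' appears (after free-text canonicalization) anywhere in the union of their
#' Ddx snapshots across stages; extraneous diagnoses neither add nor deduct.
#'
#' @param trace A `vp_trace`.
#' @param scorecard A `vp_scorecard`, or a prepared rubric from
#'   `prepare_rubric()`.
#' @param case Optional `vp_case` supplying the free-text lexicons.
#' @param max_edit_distance Passed to [match_free_text()].
#' @return Percent score in `[0, 100]`.
#' @export
score_ddx <- function(trace, scorecard, case = NULL, max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  rt <- resolve_trace(trace, rb)
  score_ddx_resolved(rt, rb)
}

score_ddx_resolved <- function(rt, rb) {
  listed <- unique(unlist(lapply(rt$snapshots, `[[`, "entries")))
  100 * sum(rb$appropriate %in% listed) / length(rb$appropriate)
}

#' Score the diagnostic-justification component
#'
#' One point for each required (datum, diagnosis) entry the learner assigned
#' with the rubric's direction; `wrong_assignment_deduction` points off for
#' each assignment that is rubric-labeled wrong or that contradicts a
#' required direction; neutral assignments score zero. The raw total is
#' clamped at zero and expressed as a percent of the number of required
#' entries.
#'
#' @inheritParams score_ddx
#' @return Percent score in `[0, 100]`.
#' @export
score_dxj <- function(trace, scorecard, case = NULL, max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  rt <- resolve_trace(trace, rb)
  score_dxj_resolved(rt, rb)
}

score_dxj_resolved <- function(rt, rb) {
  a <- rt$assignments
  n_req <- length(rb$req_dir)
  if (n_req == 0) vpdx_abort("scorecard has no required justification entries")
  if (nrow(a) == 0) return(0)
  want <- rb$req_dir[a$key]                     # NA when pair not required
  correct <- !is.na(want) & want == a$direction
  contradicts <- !is.na(want) & want != a$direction
  wrong_lab <- !is.na(rb$label_map[a$key]) & rb$label_map[a$key] == "wrong"
  bad <- contradicts | wrong_lab
  # a required pair credited at most once even if both directions were tried
  n_correct <- length(unique(a$key[correct]))
  raw <- n_correct - rb$scorecard$wrong_assignment_deduction * sum(bad)
  100 * max(0, raw) / n_req
}

#' Score the test-ordering component
#'
#' Ordered tests labeled required gain a point, inappropriate tests lose a
#' point, neutral tests contribute nothing; the clamped total is a percent
#' of the required-test count. Unmatched free-text orders contribute zero.
#'
#' @inheritParams score_ddx
#' @return Percent score in `[0, 100]`.
#' @export
score_investigations <- function(trace, scorecard, case = NULL,
                                 max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  rt <- resolve_trace(trace, rb)
  score_investigations_resolved(rt, rb)
}

score_investigations_resolved <- function(rt, rb) {
  n_req <- length(rb$required_tests)
  if (n_req == 0) vpdx_abort("scorecard has no required tests")
  raw <- sum(rt$ordered_tests %in% rb$required_tests) -
    sum(rt$ordered_tests %in% rb$inappropriate_tests)
  100 * max(0, raw) / n_req
}

#' Score the final diagnosis
#'
#' Full credit (1) when the final most-probable diagnosis matches the
#' correct one; `second_choice_credit` when the correct diagnosis is the
#' second-listed entry of the final differential; otherwise 0.
#'
#' @inheritParams score_ddx
#' @return Points in `{0, second_choice_credit, 1}`.
#' @export
score_final_dx <- function(trace, scorecard, case = NULL, max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  rt <- resolve_trace(trace, rb)
  score_final_dx_resolved(rt, rb)
}

score_final_dx_resolved <- function(rt, rb) {
  if (!is.na(rt$final) && rt$final == rb$correct) return(1)
  fin <- Filter(function(s) s$stage == "investigations", rt$snapshots)
  if (length(fin)) {
    ent <- fin[[length(fin)]]$entries
    if (length(ent) >= 2 && !is.na(ent[2]) && ent[2] == rb$correct) {
      return(rb$scorecard$second_choice_credit)
    }
  }
  0
}

#' Compute ordering penalties
#'
#' Learners lose points for exceeding the allowed number of tests or rounds
#' (threshold typically twice the cohort mean, rounded up; a count equal to
#' the threshold is not penalized), for ordering tests whose results they
#' never used in a justification, and for ordering rubric-inappropriate
#' tests.
#'
#' @inheritParams score_ddx
#' @param cohort_stats List with `mean_tests` and `mean_rounds`, required
#'   when the scorecard thresholds are `"auto"`. See [compute_cohort_stats()].
#' @return A list of class `vp_penalties` with logical `excess_tests`,
#'   `excess_rounds`, counts `unused_results_count`,
#'   `inappropriate_tests_count`, and `total_penalty_points`.
#' @export
compute_penalties <- function(trace, scorecard, cohort_stats = NULL,
                              case = NULL, max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  rt <- resolve_trace(trace, rb)
  compute_penalties_resolved(rt, rb, cohort_stats)
}

penalty_threshold <- function(setting, mean_value, what) {
  if (identical(setting, "auto")) {
    if (is.null(mean_value)) {
      vpdx_abort(paste0("auto ", what, " threshold requested without cohort_stats"),
                 class = "vpdx_config_error")
    }
    ceiling(2 * mean_value)
  } else {
    setting
  }
}

compute_penalties_resolved <- function(rt, rb, cohort_stats = NULL) {
  sc <- rb$scorecard
  thr_tests <- penalty_threshold(sc$max_tests_threshold, cohort_stats$mean_tests,
                                 "tests")
  thr_rounds <- penalty_threshold(sc$max_rounds_threshold, cohort_stats$mean_rounds,
                                  "rounds")
  used <- unique(rt$assignments$datum_id)
  unused <- setdiff(rt$ordered_tests, used)
  inapp <- intersect(rt$ordered_tests, rb$inappropriate_tests)
  w <- sc$penalty_weights
  excess_tests <- rt$n_test_orders > thr_tests
  excess_rounds <- rt$n_rounds > thr_rounds
  structure(list(
    excess_tests = excess_tests,
    excess_rounds = excess_rounds,
    unused_results_count = length(unused),
    inappropriate_tests_count = length(inapp),
    total_penalty_points =
      w$excess_tests * excess_tests + w$excess_rounds * excess_rounds +
      w$unused_result * length(unused) + w$inappropriate_test * length(inapp)
  ), class = "vp_penalties")
}

#' Cohort means used for auto penalty thresholds
#'
#' @param traces List of `vp_trace` objects.
#' @return List with `mean_tests` (orders per case) and `mean_rounds`.
#' @export
compute_cohort_stats <- function(traces) {
  nt <- vapply(traces, function(tr) nrow(tr$test_orders), numeric(1))
  nr <- vapply(traces, function(tr) length(unique(tr$test_orders$round_index)),
               numeric(1))
  list(mean_tests = mean(nt), mean_rounds = mean(nr))
}

#' Navigation metrics for one trace
#'
#' Total minutes spent and number of visits for the history, physical and
#' investigations stages.
#'
#' @param trace A `vp_trace`.
#' @return Named list `time_history`, `time_physical`, `time_investigations`
#'   (minutes) and `views_history`, `views_physical`,
#'   `views_investigations`.
#' @export
compute_navigation_metrics <- function(trace) {
  nav <- trace$navigation_events
  out <- list()
  ent <- if (nrow(nav)) parse_times(nav$enter_time) else numeric()
  ext <- if (nrow(nav)) parse_times(nav$exit_time) else numeric()
  if (any(ext < ent)) vpdx_abort("navigation_events: exit before enter")
  for (st in c("history", "physical", "investigations")) {
    i <- which(nav$stage == st)
    out[[paste0("time_", st)]] <- sum(ext[i] - ent[i]) / 60
    out[[paste0("views_", st)]] <- length(i)
  }
  out
}

#' Score one trace against its scorecard
#'
#' Assembles every component score, the final-diagnosis credit, the penalty
#' record, the five cognitive-error flags and the navigation metrics into a
#' single per-case score record (the ~125-datapoint derived record).
#' Deterministic given its inputs.
#'
#' @inheritParams compute_penalties
#' @param thresholds Cognitive-error thresholds, see [error_thresholds()].
#' @param fold_penalties If `TRUE`, penalty points (on the 0-10 component
#'   scale) are subtracted from the test-ordering percent (10 percentage
#'   points per penalty point); by default penalties are reported separately.
#' @return A list of class `vp_case_score`; `as.data.frame()` yields the one
#'   analysis row.
#' @export
score_case <- function(trace, scorecard, cohort_stats = NULL, case = NULL,
                       thresholds = error_thresholds(),
                       max_edit_distance = 0, fold_penalties = FALSE) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  rt <- resolve_trace(trace, rb)
  pen <- compute_penalties_resolved(rt, rb, cohort_stats)
  flags <- detect_all_resolved(rt, rb, thresholds)
  nav <- compute_navigation_metrics(trace)
  final_pts <- score_final_dx_resolved(rt, rb)
  inv <- score_investigations_resolved(rt, rb)
  if (fold_penalties) inv <- max(0, inv - 10 * pen$total_penalty_points)
  structure(c(
    list(
      student_id = trace$student_id, school_id = trace$school_id,
      cohort = trace$cohort, case_id = trace$case_id,
      sequence_index = trace$sequence_index,
      ddx_pct = score_ddx_resolved(rt, rb),
      dxj_pct = score_dxj_resolved(rt, rb),
      inv_pct = inv,
      final_dx_points = final_pts,
      correct = final_pts == 1,
      excess_tests = pen$excess_tests,
      excess_rounds = pen$excess_rounds,
      unused_results_count = pen$unused_results_count,
      inappropriate_tests_count = pen$inappropriate_tests_count,
      total_penalty_points = pen$total_penalty_points,
      premature_closure = flags$premature_closure,
      failure_to_rule_out = flags$failure_to_rule_out,
      confirmation_bias = flags$confirmation_bias,
      anchoring = flags$anchoring,
      search_satisficing = flags$search_satisficing,
      error_count = flags$error_count,
      n_tests = rt$n_test_orders,
      n_rounds = rt$n_rounds
    ),
    nav
  ), class = "vp_case_score", evidence = flags$evidence)
}

#' @export
as.data.frame.vp_case_score <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Score a stream of traces into a cohort dataset
#'
#' @param traces List of `vp_trace` objects.
#' @param scorecards A single `vp_scorecard` or a list keyed by `case_id`.
#' @param cases Optional matching `vp_case` list keyed by `case_id`.
#' @param cohort_stats `"auto"` (computed from `traces`; the default) or a
#'   list as in [compute_penalties()].
#' @inheritParams score_case
#' @return A cohort dataset tibble, see [as_cohort_dataset()].
#' @export
score_traces <- function(traces, scorecards, cases = NULL,
                         cohort_stats = "auto",
                         thresholds = error_thresholds(),
                         max_edit_distance = 0, fold_penalties = FALSE) {
  if (inherits(scorecards, "vp_scorecard")) scorecards <- list(scorecards)
  if (inherits(cases, "vp_case")) cases <- list(cases)
  sc_by_id <- setNames(scorecards,
                       vapply(scorecards, `[[`, "", "case_id"))
  case_by_id <- if (!is.null(cases))
    setNames(cases, vapply(cases, `[[`, "", "case_id")) else list()
  if (identical(cohort_stats, "auto")) cohort_stats <- compute_cohort_stats(traces)
  rubrics <- lapply(sc_by_id, function(sc) {
    prepare_rubric(sc, case_by_id[[sc$case_id]], max_edit_distance)
  })
  rows <- lapply(traces, function(tr) {
    rb <- rubrics[[tr$case_id]]
    if (is.null(rb)) vpdx_abort(paste0("no scorecard for case '", tr$case_id, "'"))
    as.data.frame(score_case(tr, rb, cohort_stats = cohort_stats,
                             thresholds = thresholds,
                             fold_penalties = fold_penalties))
  })
  as_cohort_dataset(rows)
}
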