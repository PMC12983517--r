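# Rule-based detectors for five cognitive-error behaviors, operating on the
# canonicalized trace (DxJ assignments, Ddx snapshots, test orders) and the
# rubric's justification labels. Three of the five (premature closure,
# failure to rule out, confirmation bias) consume only DxJ assignments plus
# scorecard labels. Every raised flag carries machine-readable evidence.

#' Thresholds for the cognitive-error detectors
#'
#' @param confirm_fraction Minimum fraction (in `(0,1]`) of a diagnosis's
#'   supporting evidence that must be engaged to escape a premature-closure
#'   flag. Default 0.5.
#' @param ruleout_fraction Analogous fraction for ruling out a competitor.
#'   Default 0.5.
#' @param bias_min_count Minimum number of contradiction-as-support
#'   assignments to flag confirmation bias. Default 1.
#' @param anchor_min_contradictions Minimum number of revealed contradicting
#'   data for anchoring. Default 2.
#' @param anchor_min_stages Minimum consecutive stage transitions holding the
#'   same leading diagnosis. Default 2.
#' @param satisfice_min_ddx Minimum differential size after the history stage
#'   to escape a search-satisficing flag. Default 3.
#' @return A list of class `vp_error_thresholds`.
#' @export
error_thresholds <- function(confirm_fraction = 0.5,
                             ruleout_fraction = 0.5,
                             bias_min_count = 1,
                             anchor_min_contradictions = 2,
                             anchor_min_stages = 2,
                             satisfice_min_ddx = 3) {
  if (confirm_fraction <= 0 || confirm_fraction > 1) {
    vpdx_abort("confirm_fraction must be in (0, 1]")
  }
  if (ruleout_fraction <= 0 || ruleout_fraction > 1) {
    vpdx_abort("ruleout_fraction must be in (0, 1]")
  }
  if (bias_min_count < 1 || anchor_min_contradictions < 1 ||
      anchor_min_stages < 1 || satisfice_min_ddx < 1) {
    vpdx_abort("count thresholds must be >= 1")
  }
  structure(list(
    confirm_fraction = confirm_fraction,
    ruleout_fraction = ruleout_fraction,
    bias_min_count = bias_min_count,
    anchor_min_contradictions = anchor_min_contradictions,
    anchor_min_stages = anchor_min_stages,
    satisfice_min_ddx = satisfice_min_ddx
  ), class = "vp_error_thresholds")
}

# supporting evidence for a diagnosis: required_increase data; confirmatory
# tests are rubric-required tests linked "confirms"
dx_support <- function(rb, dx) {
  req <- rb$req_df
  data_ids <- req$datum_id[req$diagnosis == dx & req$label == "required_increase"]
  lk <- rb$test_links
  tests <- intersect(lk$test_id[lk$diagnosis == dx & lk$link == "confirms"],
                     rb$required_tests)
  list(data = data_ids, tests = tests)
}

dx_ruleout <- function(rb, dx) {
  req <- rb$req_df
  data_ids <- req$datum_id[req$diagnosis == dx & req$label == "required_decrease"]
  lk <- rb$test_links
  tests <- intersect(lk$test_id[lk$diagnosis == dx & lk$link == "rules_out"],
                     rb$required_tests)
  list(data = data_ids, tests = tests)
}

assigned_with_dir <- function(rt, data_ids, dx, dir) {
  a <- rt$assignments
  data_ids[data_ids %in% a$datum_id[a$diagnosis == dx & a$direction == dir]]
}

#' Detect failure to confirm the chosen diagnosis (premature closure)
#'
#' Flags a case where the learner committed to a final diagnosis while
#' having engaged less than `confirm_fraction` of its required supporting
#' data in their justifications and ordered less than `confirm_fraction` of
#' its confirmatory tests. A clause with an empty denominator (the rubric
#' defines no supporting data, or no confirmatory tests, for that
#' diagnosis) is vacuous and cannot be violated; if the rubric defines no
#' confirmatory evidence of either kind the case is not assessable and is
#' not flagged.
#'
#' @inheritParams score_ddx
#' @param thresholds See [error_thresholds()].
#' @return List with `flag` (logical) and `evidence` (character vector of
#'   rule clauses, non-empty whenever `flag` is `TRUE`).
#' @export
detect_premature_closure <- function(trace, scorecard, case = NULL,
                                     thresholds = error_thresholds(),
                                     max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  detect_premature_closure_resolved(resolve_trace(trace, rb), rb, thresholds)
}

frac0 <- function(num, den) if (den == 0) 0 else num / den

detect_premature_closure_resolved <- function(rt, rb, th) {
  fin <- rt$final
  if (is.na(fin)) fin <- "(unrecognized diagnosis)"
  sup <- dx_support(rb, fin)
  got_data <- assigned_with_dir(rt, sup$data, fin, "increases")
  got_tests <- intersect(sup$tests, rt$ordered_tests)
  fracs <- c(
    if (length(sup$data)) length(got_data) / length(sup$data),
    if (length(sup$tests)) length(got_tests) / length(sup$tests))
  flag <- length(fracs) > 0 && all(fracs < th$confirm_fraction)
  ev <- character()
  if (flag) {
    ev <- c(
      if (length(sup$data))
        sprintf("final diagnosis '%s': %d/%d supporting data assigned (< %.2f)",
                fin, length(got_data), length(sup$data), th$confirm_fraction),
      if (length(sup$tests))
        sprintf("final diagnosis '%s': %d/%d confirmatory tests ordered (< %.2f)",
                fin, length(got_tests), length(sup$tests), th$confirm_fraction),
      if (length(setdiff(sup$data, got_data)))
        paste0("missing data: ", paste(setdiff(sup$data, got_data), collapse = ", ")),
      if (length(setdiff(sup$tests, got_tests)))
        paste0("missing tests: ", paste(setdiff(sup$tests, got_tests), collapse = ", "))
    )
  }
  list(flag = flag, evidence = ev)
}

#' Detect failure to rule out a competing diagnosis
#'
#' Flags a case where some rubric-appropriate competitor (distinct from the
#' final diagnosis) that the learner themselves listed in a differential was
#' never ruled out: less than `ruleout_fraction` of its required
#' rule-out data were assigned and none of its discriminating required tests
#' were ordered. Competitors never listed are the Ddx score's concern, not
#' this detector's; competitors with no rule-out evidence in the rubric are
#' not flaggable.
#'
#' @inheritParams detect_premature_closure
#' @export
detect_failure_to_rule_out <- function(trace, scorecard, case = NULL,
                                       thresholds = error_thresholds(),
                                       max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  detect_failure_to_rule_out_resolved(resolve_trace(trace, rb), rb, thresholds)
}

detect_failure_to_rule_out_resolved <- function(rt, rb, th) {
  listed <- unique(unlist(lapply(rt$snapshots, `[[`, "entries")))
  competitors <- setdiff(intersect(rb$appropriate, listed), rt$final)
  ev <- character()
  for (dx in competitors) {
    ro <- dx_ruleout(rb, dx)
    if (length(ro$data) == 0 && length(ro$tests) == 0) next
    got_data <- assigned_with_dir(rt, ro$data, dx, "decreases")
    got_tests <- intersect(ro$tests, rt$ordered_tests)
    if (frac0(length(got_data), length(ro$data)) < th$ruleout_fraction &&
        length(got_tests) == 0) {
      ev <- c(ev, sprintf(
        "competitor '%s' listed but not ruled out: %d/%d rule-out data assigned, 0/%d discriminating tests ordered",
        dx, length(got_data), length(ro$data), length(ro$tests)))
    }
  }
  list(flag = length(ev) > 0, evidence = ev)
}

#' Detect confirmation bias
#'
#' Flags a case with at least `bias_min_count` justification assignments in
#' which the learner marked a datum as *increasing* one of their leading
#' (most-probable) diagnoses when the rubric labels that pair
#' `required_decrease` or `wrong` -- i.e. contradicting evidence read as
#' support. Contradicting assignments to non-leading diagnoses are not
#' counted.
#'
#' @inheritParams detect_premature_closure
#' @export
detect_confirmation_bias <- function(trace, scorecard, case = NULL,
                                     thresholds = error_thresholds(),
                                     max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  detect_confirmation_bias_resolved(resolve_trace(trace, rb), rb, thresholds)
}

detect_confirmation_bias_resolved <- function(rt, rb, th) {
  leading <- unique(na.omit(vapply(rt$snapshots, `[[`, "", "most_probable")))
  a <- rt$assignments
  i <- which(a$direction == "increases" & a$diagnosis %in% leading)
  lab <- rb$label_map[a$key[i]]
  hit <- i[!is.na(lab) & lab %in% c("required_decrease", "wrong")]
  flag <- length(hit) >= th$bias_min_count
  ev <- if (flag) {
    sprintf("datum '%s' marked as increasing leading diagnosis '%s' but rubric labels it %s",
            a$datum_id[hit], a$diagnosis[hit], rb$label_map[a$key[hit]])
  } else character()
  list(flag = flag, evidence = ev)
}

# ordinal position of a navigation stage
stage_rank <- function(stage) match(stage, NAV_STAGES)

# required_decrease data for dx revealed by the time a snapshot at `stage`
# is taken: findings from stages already presented, plus results of tests
# the learner had ordered (investigations stage)
revealed_contradictions <- function(rt, rb, dx, stage) {
  req <- rb$req_df
  ids <- req$datum_id[req$diagnosis == dx & req$label == "required_decrease"]
  keep <- vapply(ids, function(id) {
    st <- rb$finding_stage[id]
    if (!is.null(st) && !is.na(st)) {
      stage_rank(unname(st)) <= stage_rank(stage)
    } else {
      # test-result datum: revealed only if ordered, in the investigations stage
      stage_rank(stage) >= stage_rank("investigations") && id %in% rt$ordered_tests
    }
  }, logical(1))
  ids[keep]
}

#' Detect anchoring
#'
#' Flags a case where the learner held the same incorrect diagnosis as most
#' probable for at least `anchor_min_stages` consecutive stage transitions
#' while at least `anchor_min_contradictions` required rule-out data for it
#' had already been revealed, and still chose that diagnosis as final.
#'
#' @inheritParams detect_premature_closure
#' @export
detect_anchoring <- function(trace, scorecard, case = NULL,
                             thresholds = error_thresholds(),
                             max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  detect_anchoring_resolved(resolve_trace(trace, rb), rb, thresholds)
}

detect_anchoring_resolved <- function(rt, rb, th) {
  mp <- vapply(rt$snapshots, `[[`, "", "most_probable")
  stages <- vapply(rt$snapshots, `[[`, "", "stage")
  fin <- rt$final
  if (is.na(fin) || !length(mp) || fin == rb$correct) {
    return(list(flag = FALSE, evidence = character()))
  }
  r <- rle(ifelse(is.na(mp), "\r", mp))
  ends <- cumsum(r$lengths)
  ev <- character()
  for (j in which(r$values == fin & r$lengths >= th$anchor_min_stages)) {
    contr <- revealed_contradictions(rt, rb, fin, stages[ends[j]])
    if (length(contr) >= th$anchor_min_contradictions) {
      ev <- c(ev, sprintf(
        "'%s' held as most probable for %d consecutive stages and chosen as final despite %d revealed contradicting data (%s)",
        fin, r$lengths[j], length(contr), paste(contr, collapse = ", ")))
    }
  }
  list(flag = length(ev) > 0, evidence = ev)
}

#' Detect search satisficing
#'
#' Flags a case where the differential after the history stage held fewer
#' than `satisfice_min_ddx` diagnoses and less than half of the
#' rubric-appropriate diagnoses were ever listed -- the learner stopped
#' generating hypotheses once one candidate seemed plausible.
#'
#' @inheritParams detect_premature_closure
#' @export
detect_search_satisficing <- function(trace, scorecard, case = NULL,
                                      thresholds = error_thresholds(),
                                      max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  detect_search_satisficing_resolved(resolve_trace(trace, rb), rb, thresholds)
}

detect_search_satisficing_resolved <- function(rt, rb, th) {
  hist <- Filter(function(s) s$stage == "history", rt$snapshots)
  snap <- if (length(hist)) hist[[length(hist)]]
          else if (length(rt$snapshots)) rt$snapshots[[1]] else NULL
  size <- if (is.null(snap)) 0 else length(snap$raw_entries)
  listed <- unique(unlist(lapply(rt$snapshots, `[[`, "entries")))
  frac_appropriate <- frac0(sum(rb$appropriate %in% listed), length(rb$appropriate))
  flag <- size < th$satisfice_min_ddx && frac_appropriate < 0.5
  ev <- if (flag) {
    sprintf("differential after history held %d (< %d) entries and only %d/%d appropriate diagnoses were ever listed",
            size, th$satisfice_min_ddx, sum(rb$appropriate %in% listed),
            length(rb$appropriate))
  } else character()
  list(flag = flag, evidence = ev)
}

#' Run all five cognitive-error detectors
#'
#' @inheritParams detect_premature_closure
#' @return A list of class `vp_error_flags`: the five logical flags,
#'   `error_count`, and an `evidence` list keyed by error name.
#' @export
detect_all <- function(trace, scorecard, case = NULL,
                       thresholds = error_thresholds(),
                       max_edit_distance = 0) {
  rb <- prepare_rubric(scorecard, case, max_edit_distance)
  detect_all_resolved(resolve_trace(trace, rb), rb, thresholds)
}

detect_all_resolved <- function(rt, rb, th) {
  res <- list(
    premature_closure = detect_premature_closure_resolved(rt, rb, th),
    failure_to_rule_out = detect_failure_to_rule_out_resolved(rt, rb, th),
    confirmation_bias = detect_confirmation_bias_resolved(rt, rb, th),
    anchoring = detect_anchoring_resolved(rt, rb, th),
    search_satisficing = detect_search_satisficing_resolved(rt, rb, th)
  )
  flags <- vapply(res, `[[`, logical(1), "flag")
  structure(c(as.list(flags),
              list(error_count = sum(flags),
                   evidence = lapply(res, `[[`, "evidence"))),
            class = "vp_error_flags")
}
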