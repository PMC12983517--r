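# Domain types for staged virtual-patient encounters: clinical cases,
# expert scorecards, student interaction traces, and the long score table.
# All objects are plain lists/data.frames with a class attribute and a
# validator; serialization is JSON (single documents), JSON-Lines (trace
# streams) and CSV (score tables).

VP_STAGES <- c("history", "physical")
NAV_STAGES <- c("intro", "history", "physical", "investigations")
DXJ_LABELS <- c("required_increase", "required_decrease", "neutral", "wrong")
TEST_LABELS <- c("required", "neutral", "inappropriate")
DIRECTIONS <- c("increases", "decreases")

#' Construct a clinical case
#'
#' A case is presented to the learner in four stages (one-sentence
#' introduction, history, physical exam, investigations). Findings belong to
#' the history or physical stage; test results are revealed only when the
#' learner orders the test. The diagnosis lexicon maps canonical diagnosis
#' labels to the free-text synonyms a learner may type.
#'
#' @param case_id Unique case identifier.
#' @param intro One-sentence stem shown before the history stage.
#' @param findings Data frame with columns `finding_id`, `stage`
#'   (`"history"` or `"physical"`) and `text`.
#' @param tests Data frame with columns `test_id`, `name`, `synonyms`
#'   (list column of character vectors) and `result`.
#' @param correct_diagnosis Canonical label of the case's true diagnosis;
#'   must appear in `diagnosis_lexicon`.
#' @param diagnosis_lexicon Named list mapping canonical diagnosis labels to
#'   character vectors of accepted synonyms.
#' @return An object of class `vp_case`.
#' @export
vp_case <- function(case_id, intro, findings, tests, correct_diagnosis,
                    diagnosis_lexicon) {
  x <- structure(
    list(
      case_id = as.character(case_id),
      intro = as.character(intro),
      findings = as.data.frame(findings),
      tests = as.data.frame(tests),
      correct_diagnosis = as.character(correct_diagnosis),
      diagnosis_lexicon = diagnosis_lexicon
    ),
    class = "vp_case"
  )
  validate_vp_case(x)
}

#' @rdname vp_case
#' @param x Object to validate.
#' @export
validate_vp_case <- function(x) {
  f <- x$findings
  need <- c("finding_id", "stage", "text")
  if (!all(need %in% names(f))) {
    vpdx_abort(paste0("findings: missing column(s) ",
                      paste(setdiff(need, names(f)), collapse = ", ")))
  }
  if (anyDuplicated(f$finding_id)) vpdx_abort("findings: finding_id not unique")
  if (!all(f$stage %in% VP_STAGES)) {
    vpdx_abort("findings: stage must be 'history' or 'physical'")
  }
  tt <- x$tests
  need <- c("test_id", "name", "synonyms", "result")
  if (!all(need %in% names(tt))) {
    vpdx_abort(paste0("tests: missing column(s) ",
                      paste(setdiff(need, names(tt)), collapse = ", ")))
  }
  if (anyDuplicated(tt$test_id)) vpdx_abort("tests: test_id not unique")
  if (any(!nzchar(tt$result))) vpdx_abort("tests: result must be non-empty")
  if (any(lengths(tt$synonyms) == 0)) vpdx_abort("tests: synonyms must be non-empty")
  if (length(x$diagnosis_lexicon) == 0 || is.null(names(x$diagnosis_lexicon))) {
    vpdx_abort("diagnosis_lexicon: must be a non-empty named list")
  }
  if (!x$correct_diagnosis %in% names(x$diagnosis_lexicon)) {
    vpdx_abort("correct_diagnosis: not present in diagnosis_lexicon")
  }
  # canonical column order so documents round-trip to equal values
  fc <- c("finding_id", "stage", "text")
  x$findings <- x$findings[c(fc, setdiff(names(x$findings), fc))]
  tc <- c("test_id", "name", "synonyms", "result")
  x$tests <- x$tests[c(tc, setdiff(names(x$tests), tc))]
  x
}

#' Construct an expert scorecard
#'
#' The scorecard is the per-case rubric driving automated scoring: the set of
#' diagnoses judged appropriate for the case, labels for each
#' (datum, diagnosis) justification pair, labels for each orderable test,
#' optional links tying tests to the diagnoses they confirm or rule out, and
#' the penalty configuration.
#'
#' @param case_id Case the rubric belongs to.
#' @param appropriate_diagnoses Character vector (>= 3 canonical labels is
#'   typical) of diagnoses credited in the differential.
#' @param correct_diagnosis Canonical label of the true diagnosis; must be in
#'   `appropriate_diagnoses`.
#' @param dxj_labels Data frame with columns `datum_id` (a finding or test
#'   id), `diagnosis` (canonical label) and `label`, one of
#'   `"required_increase"`, `"required_decrease"`, `"neutral"`, `"wrong"`.
#'   Pairs not listed are treated as neutral.
#' @param test_labels Data frame with columns `test_id` and `label`, one of
#'   `"required"`, `"neutral"`, `"inappropriate"`.
#' @param test_links Data frame with columns `test_id`, `diagnosis`, `link`
#'   (`"confirms"` or `"rules_out"`), used by the cognitive-error detectors.
#' @param second_choice_credit Credit (in (0,1)) for listing the correct
#'   diagnosis second in the final differential. Default 0.5.
#' @param wrong_assignment_deduction Points deducted (in (0,1]) per incorrect
#'   justification assignment. Default 0.5.
#' @param max_tests_threshold,max_rounds_threshold Positive integer caps, or
#'   `"auto"` for twice the cohort mean (rounded up).
#' @param penalty_weights Named list of point values: `excess_tests`,
#'   `excess_rounds`, `unused_result` (per test), `inappropriate_test`
#'   (per test).
#' @return An object of class `vp_scorecard`.
#' @export
vp_scorecard <- function(case_id, appropriate_diagnoses, correct_diagnosis,
                         dxj_labels, test_labels,
                         test_links = empty_test_links(),
                         second_choice_credit = 0.5,
                         wrong_assignment_deduction = 0.5,
                         max_tests_threshold = "auto",
                         max_rounds_threshold = "auto",
                         penalty_weights = default_penalty_weights()) {
  x <- structure(
    list(
      case_id = as.character(case_id),
      appropriate_diagnoses = as.character(appropriate_diagnoses),
      correct_diagnosis = as.character(correct_diagnosis),
      dxj_labels = as.data.frame(dxj_labels),
      test_labels = as.data.frame(test_labels),
      test_links = as.data.frame(test_links),
      second_choice_credit = second_choice_credit,
      wrong_assignment_deduction = wrong_assignment_deduction,
      max_tests_threshold = max_tests_threshold,
      max_rounds_threshold = max_rounds_threshold,
      penalty_weights = penalty_weights
    ),
    class = "vp_scorecard"
  )
  validate_vp_scorecard(x)
}

#' @export
default_penalty_weights <- function() {
  list(excess_tests = 1, excess_rounds = 1,
       unused_result = 0.5, inappropriate_test = 0.5)
}

empty_test_links <- function() {
  data.frame(test_id = character(), diagnosis = character(),
             link = character(), stringsAsFactors = FALSE)
}

#' @rdname vp_scorecard
#' @param x Object to validate.
#' @export
validate_vp_scorecard <- function(x) {
  if (!x$correct_diagnosis %in% x$appropriate_diagnoses) {
    vpdx_abort("correct_diagnosis: not in appropriate_diagnoses")
  }
  dl <- x$dxj_labels
  need <- c("datum_id", "diagnosis", "label")
  if (!all(need %in% names(dl))) {
    vpdx_abort(paste0("dxj_labels: missing column(s) ",
                      paste(setdiff(need, names(dl)), collapse = ", ")))
  }
  if (!all(dl$label %in% DXJ_LABELS)) {
    vpdx_abort("dxj_labels: label must be one of required_increase, required_decrease, neutral, wrong")
  }
  if (anyDuplicated(paste(dl$datum_id, dl$diagnosis))) {
    vpdx_abort("dxj_labels: duplicated (datum_id, diagnosis) pair")
  }
  ri <- dl$label == "required_increase" & dl$diagnosis == x$correct_diagnosis
  if (!any(ri)) {
    vpdx_abort("dxj_labels: need at least one required_increase entry for the correct diagnosis")
  }
  tl <- x$test_labels
  if (!all(c("test_id", "label") %in% names(tl))) {
    vpdx_abort("test_labels: need columns test_id, label")
  }
  if (!all(tl$label %in% TEST_LABELS)) {
    vpdx_abort("test_labels: label must be one of required, neutral, inappropriate")
  }
  lk <- x$test_links
  if (nrow(lk) && !all(lk$link %in% c("confirms", "rules_out"))) {
    vpdx_abort("test_links: link must be 'confirms' or 'rules_out'")
  }
  if (!is.numeric(x$second_choice_credit) ||
      x$second_choice_credit <= 0 || x$second_choice_credit >= 1) {
    vpdx_abort("second_choice_credit: must be in (0, 1)")
  }
  if (x$wrong_assignment_deduction <= 0 || x$wrong_assignment_deduction > 1) {
    vpdx_abort("wrong_assignment_deduction: must be in (0, 1]")
  }
  for (fld in c("max_tests_threshold", "max_rounds_threshold")) {
    v <- x[[fld]]
    ok <- identical(v, "auto") || (is.numeric(v) && length(v) == 1 && v > 0)
    if (!ok) vpdx_abort(paste0(fld, ": must be 'auto' or a positive count"))
  }
  wnames <- c("excess_tests", "excess_rounds", "unused_result", "inappropriate_test")
  if (!all(wnames %in% names(x$penalty_weights))) {
    vpdx_abort("penalty_weights: missing weight(s)")
  }
  x
}

#' Construct a student trace
#'
#' The full event log of one student completing one case: the differential
#' diagnosis (Ddx) snapshot recorded at each stage transition (at most five
#' free-text conditions, first entry = flagged most-probable diagnosis),
#' diagnostic-justification (DxJ) assignments of data to diagnoses, test
#' orders grouped in "Get Results" rounds, stage navigation intervals, and
#' the final diagnosis with a certainty rating.
#'
#' @param student_id,school_id Identifiers.
#' @param cohort `"M1"` or `"M2"`.
#' @param case_id Case completed.
#' @param sequence_index Position of this case in the student's sequence
#'   (1-based, at most 20).
#' @param ddx_snapshots List of snapshots, each a list with `stage` (one of
#'   `"intro"`, `"history"`, `"physical"`, `"investigations"`), `entries`
#'   (character vector, length <= 5) and `most_probable` (single string,
#'   by convention `entries[1]`).
#' @param dxj_assignments Data frame with columns `datum_id`, `diagnosis`
#'   (free text), `direction` (`"increases"`/`"decreases"`) and `timestamp`
#'   (seconds from case start, or ISO-8601 string).
#' @param test_orders Data frame with columns `test_text` (free text) and
#'   `round_index` (contiguous from 1).
#' @param navigation_events Data frame with columns `stage`, `enter_time`,
#'   `exit_time` (seconds from case start, or ISO-8601 strings).
#' @param final_diagnosis Free-text final most-probable diagnosis.
#' @param certainty Ordinal certainty 1-5 (recorded, not scored).
#' @param validate Set `FALSE` to skip invariant checks (used by the
#'   simulator on traces it constructs itself).
#' @return An object of class `vp_trace`.
#' @export
vp_trace <- function(student_id, school_id, cohort, case_id, sequence_index,
                     ddx_snapshots, dxj_assignments, test_orders,
                     navigation_events, final_diagnosis, certainty = 3L,
                     validate = TRUE) {
  x <- structure(
    list(
      student_id = as.character(student_id),
      school_id = as.character(school_id),
      cohort = as.character(cohort),
      case_id = as.character(case_id),
      sequence_index = as.integer(sequence_index),
      ddx_snapshots = ddx_snapshots,
      dxj_assignments = as.data.frame(dxj_assignments),
      test_orders = as.data.frame(test_orders),
      navigation_events = as.data.frame(navigation_events),
      final_diagnosis = as.character(final_diagnosis),
      certainty = as.integer(certainty)
    ),
    class = "vp_trace"
  )
  if (validate) validate_vp_trace(x) else x
}

#' @rdname vp_trace
#' @export
validate_vp_trace <- function(x) {
  if (!x$cohort %in% c("M1", "M2")) vpdx_abort("cohort: must be 'M1' or 'M2'")
  if (is.na(x$sequence_index) || x$sequence_index < 1) {
    vpdx_abort("sequence_index: must be >= 1")
  }
  for (snap in x$ddx_snapshots) {
    if (!snap$stage %in% NAV_STAGES) vpdx_abort("ddx_snapshots: unknown stage")
    if (length(snap$entries) > 5) {
      vpdx_abort("ddx_snapshots: a differential may hold at most 5 diagnoses")
    }
    if (length(snap$entries) > 0 && !identical(snap$most_probable, snap$entries[[1]])) {
      vpdx_abort("ddx_snapshots: most_probable must be the first-listed entry")
    }
  }
  to <- x$test_orders
  if (!all(c("test_text", "round_index") %in% names(to))) {
    vpdx_abort("test_orders: need columns test_text, round_index")
  }
  if (nrow(to)) {
    rounds <- sort(unique(to$round_index))
    if (!identical(as.integer(rounds), seq_along(rounds))) {
      vpdx_abort("test_orders: round_index must be contiguous from 1")
    }
  }
  da <- x$dxj_assignments
  if (!all(c("datum_id", "diagnosis", "direction") %in% names(da))) {
    vpdx_abort("dxj_assignments: need columns datum_id, diagnosis, direction")
  }
  if (nrow(da) && !all(da$direction %in% DIRECTIONS)) {
    vpdx_abort("dxj_assignments: direction must be 'increases' or 'decreases'")
  }
  nav <- x$navigation_events
  if (nrow(nav)) {
    ent <- parse_times(nav$enter_time)
    ext <- parse_times(nav$exit_time)
    if (any(ext < ent)) vpdx_abort("navigation_events: exit before enter")
    o <- order(ent)
    if (any(ent[o][-1] < ext[o][-length(o)] - 1e-9)) {
      vpdx_abort("navigation_events: overlapping intervals")
    }
  }
  x
}

# numeric seconds pass through; ISO-8601 strings are parsed to epoch seconds
parse_times <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- is.na(t) & !is.na(x)
  if (any(bad)) vpdx_abort(paste0("unparseable timestamp: ", x[bad][1]))
  as.numeric(t)
}

# ---- free-text matching -----------------------------------------------------

#' Normalize free text for matching
#'
#' Case-folds, strips punctuation, and collapses internal/outer whitespace.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Build a lookup index from a diagnosis lexicon
#'
#' @param lexicon Named list mapping canonical labels to synonym vectors.
#' @return Named character vector: normalized synonym -> canonical label,
#'   ordered by canonical label so matching is deterministic.
#' @export
lexicon_index <- function(lexicon) {
  canon <- names(lexicon)
  syn <- lapply(seq_along(lexicon), function(i) {
    unique(normalize_text(c(canon[i], lexicon[[i]])))
  })
  idx <- rep(canon, lengths(syn))
  names(idx) <- unlist(syn)
  # first occurrence wins on synonym collisions across labels
  idx[!duplicated(names(idx))]
}

#' Match a free-text entry against a diagnosis lexicon
#'
#' Learners enter diagnoses and tests as free text; scoring canonicalizes the
#' entry against a curated synonym lexicon. Matching normalizes both sides
#' (case, whitespace, punctuation) and is exact by default; a bounded
#' Levenshtein edit distance (<= 2 recommended) can be enabled to absorb
#' typos.
#'
#' @param entry Character vector of free-text entries.
#' @param lexicon Named list (canonical -> synonyms) or a prebuilt
#'   [lexicon_index()].
#' @param max_edit_distance Non-negative integer; 0 (default) requires an
#'   exact normalized match.
#' @return Character vector of canonical labels, `NA` where unmatched.
#' @export
match_free_text <- function(entry, lexicon, max_edit_distance = 0) {
  idx <- if (is.character(lexicon) && !is.null(names(lexicon))) lexicon
         else lexicon_index(lexicon)
  if (length(idx) == 0) vpdx_abort("lexicon must be non-empty")
  key <- normalize_text(entry)
  out <- unname(idx[key])
  if (max_edit_distance > 0 && anyNA(out)) {
    miss <- which(is.na(out) & nzchar(key))
    if (length(miss)) {
      d <- adist(key[miss], names(idx))
      for (j in seq_along(miss)) {
        dm <- d[j, ]
        if (min(dm) <= max_edit_distance) {
          # nearest synonym; ties broken by index order (canonical label order)
          out[miss[j]] <- unname(idx[which.min(dm)])
        }
      }
    }
  }
  out
}

# ---- serialization ----------------------------------------------------------

df_to_records <- function(df) {
  if (nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df, function(col) {
      v <- if (is.list(col)) col[[i]] else col[[i]]
      v
    })
    row
  })
}

records_to_df <- function(recs, cols, list_cols = character(),
                          coerce = list()) {
  if (length(recs) == 0) {
    out <- lapply(cols, function(cn) {
      if (cn %in% list_cols) return(list())
      f <- coerce[[cn]]
      if (is.null(f)) character() else f(NULL)
    })
    names(out) <- cols
    df <- as.data.frame(out[!cols %in% list_cols], stringsAsFactors = FALSE)
    for (cn in intersect(list_cols, cols)) df[[cn]] <- list()
    return(df[cols])
  }
  out <- lapply(cols, function(cn) {
    vals <- lapply(recs, function(r) r[[cn]])
    if (cn %in% list_cols) {
      lapply(vals, function(v) unlist(v, use.names = FALSE))
    } else {
      v <- unlist(lapply(vals, function(v) if (is.null(v)) NA else v),
                  use.names = FALSE)
      f <- coerce[[cn]]
      if (is.null(f)) v else f(v)
    }
  })
  names(out) <- cols
  df <- data.frame(out[!cols %in% list_cols], stringsAsFactors = FALSE)
  for (cn in intersect(list_cols, cols)) df[[cn]] <- out[[cn]]
  df[cols]
}

# timestamps may be numeric seconds or ISO-8601 strings; keep strings as-is
num_or_chr <- function(x) if (is.character(x)) x else as.numeric(x)

case_to_list <- function(x) {
  list(
    case_id = x$case_id, intro = x$intro,
    findings = df_to_records(x$findings),
    tests = df_to_records(x$tests),
    correct_diagnosis = x$correct_diagnosis,
    diagnosis_lexicon = x$diagnosis_lexicon
  )
}

case_from_list <- function(l) {
  vp_case(
    case_id = l$case_id, intro = l$intro,
    findings = records_to_df(l$findings, c("finding_id", "stage", "text")),
    tests = records_to_df(l$tests, c("test_id", "name", "synonyms", "result"),
                          list_cols = "synonyms"),
    correct_diagnosis = l$correct_diagnosis,
    diagnosis_lexicon = lapply(l$diagnosis_lexicon,
                               function(s) unlist(s, use.names = FALSE))
  )
}

scorecard_to_list <- function(x) {
  list(
    case_id = x$case_id,
    appropriate_diagnoses = x$appropriate_diagnoses,
    correct_diagnosis = x$correct_diagnosis,
    dxj_labels = df_to_records(x$dxj_labels),
    test_labels = df_to_records(x$test_labels),
    test_links = df_to_records(x$test_links),
    second_choice_credit = x$second_choice_credit,
    wrong_assignment_deduction = x$wrong_assignment_deduction,
    max_tests_threshold = x$max_tests_threshold,
    max_rounds_threshold = x$max_rounds_threshold,
    penalty_weights = x$penalty_weights
  )
}

scorecard_from_list <- function(l) {
  vp_scorecard(
    case_id = l$case_id,
    appropriate_diagnoses = unlist(l$appropriate_diagnoses, use.names = FALSE),
    correct_diagnosis = l$correct_diagnosis,
    dxj_labels = records_to_df(l$dxj_labels, c("datum_id", "diagnosis", "label")),
    test_labels = records_to_df(l$test_labels, c("test_id", "label")),
    test_links = records_to_df(l$test_links, c("test_id", "diagnosis", "link")),
    second_choice_credit = l$second_choice_credit,
    wrong_assignment_deduction = l$wrong_assignment_deduction,
    max_tests_threshold = l$max_tests_threshold,
    max_rounds_threshold = l$max_rounds_threshold,
    penalty_weights = l$penalty_weights
  )
}

trace_to_list <- function(x) {
  list(
    student_id = x$student_id, school_id = x$school_id, cohort = x$cohort,
    case_id = x$case_id, sequence_index = x$sequence_index,
    ddx_snapshots = lapply(x$ddx_snapshots, function(s) {
      list(stage = s$stage, entries = s$entries, most_probable = s$most_probable)
    }),
    dxj_assignments = df_to_records(x$dxj_assignments),
    test_orders = df_to_records(x$test_orders),
    navigation_events = df_to_records(x$navigation_events),
    final_diagnosis = x$final_diagnosis,
    certainty = x$certainty
  )
}

trace_from_list <- function(l, validate = TRUE) {
  vp_trace(
    student_id = l$student_id, school_id = l$school_id, cohort = l$cohort,
    case_id = l$case_id, sequence_index = l$sequence_index,
    ddx_snapshots = lapply(l$ddx_snapshots, function(s) {
      list(stage = s$stage,
           entries = unlist(s$entries, use.names = FALSE) %||% character(),
           most_probable = s$most_probable)
    }),
    dxj_assignments = records_to_df(
      l$dxj_assignments, c("datum_id", "diagnosis", "direction", "timestamp"),
      coerce = list(datum_id = as.character, diagnosis = as.character,
                    direction = as.character, timestamp = num_or_chr)),
    test_orders = records_to_df(
      l$test_orders, c("test_text", "round_index"),
      coerce = list(test_text = as.character, round_index = as.integer)),
    navigation_events = records_to_df(
      l$navigation_events, c("stage", "enter_time", "exit_time"),
      coerce = list(stage = as.character, enter_time = num_or_chr,
                    exit_time = num_or_chr)),
    final_diagnosis = l$final_diagnosis,
    certainty = l$certainty,
    validate = validate
  )
}

#' Read and write case, scorecard and trace documents
#'
#' Cases and scorecards are single JSON documents; traces are JSON-Lines
#' streams with one complete trace object per line. Writing then reading
#' yields an equal value.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the parsed object(s); writers return `path`
#'   invisibly.
#' @export
write_case <- function(x, path) {
  jsonlite::write_json(case_to_list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_case
#' @export
read_case <- function(path) {
  case_from_list(jsonlite::read_json(path))
}

#' @rdname write_case
#' @export
write_scorecard <- function(x, path) {
  jsonlite::write_json(scorecard_to_list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_case
#' @export
read_scorecard <- function(path) {
  scorecard_from_list(jsonlite::read_json(path))
}

#' @rdname write_case
#' @param traces List of `vp_trace` objects.
#' @export
write_traces <- function(traces, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (tr in traces) {
    writeLines(jsonlite::toJSON(trace_to_list(tr), auto_unbox = TRUE,
                                digits = NA, null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_case
#' @param validate Validate each trace on read.
#' @export
read_traces <- function(path, validate = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    trace_from_list(jsonlite::parse_json(ln), validate = validate)
  })
}

# ---- cohort dataset ---------------------------------------------------------

#' Assemble a long cohort dataset from per-case scores
#'
#' Stacks `vp_case_score` records (see [score_case()]) into the long
#' student-by-case table consumed by the analysis stage, ordered by
#' `(school_id, student_id, sequence_index)`.
#'
#' @param scores List of `vp_case_score` objects, or a data frame already in
#'   long form.
#' @return A tibble with one row per (student, case).
#' @export
as_cohort_dataset <- function(scores) {
  df <- if (is.data.frame(scores)) scores
        else dplyr::bind_rows(lapply(scores, as.data.frame))
  if (anyDuplicated(paste(df$student_id, df$case_id))) {
    vpdx_abort("cohort dataset: duplicate (student_id, case_id) row")
  }
  df <- dplyr::arrange(df, .data$school_id, .data$student_id, .data$sequence_index)
  bad <- df |>
    dplyr::group_by(.data$student_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$sequence_index, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    vpdx_abort(paste0("cohort dataset: sequence_index not strictly increasing for student ",
                      bad$student_id[1]))
  }
  tibble::as_tibble(df)
}

#' @rdname as_cohort_dataset
#' @param x Cohort dataset.
#' @param path CSV path.
#' @export
write_cohort_dataset <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname as_cohort_dataset
#' @export
read_cohort_dataset <- function(path) {
  as_cohort_dataset(read.csv(path, stringsAsFactors = FALSE))
}
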