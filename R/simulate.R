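# Synthetic learner-cohort simulator. Students carry latent skills on the
# logit scale (differential building, justification, test ordering, error
# proneness) with school effects, practice-driven growth along log(case
# sequence), and a shared AR(1) "form" residual across a student's case
# sequence. Each (student, case) draws full interaction behavior -- Ddx
# snapshots, justification assignments, test rounds, navigation -- and the
# final diagnosis is drawn from a logistic link on the realized component
# performance and error behaviors.

#' Frozen calibration constants of the default generator
#'
#' Intercepts/slopes (logit scale) of the four latent skill trajectories,
#' the correctness-link coefficients, and the behavior multipliers. The
#' defaults were solved once (Monte-Carlo root finding against the
#' generator's own first/last-case marginals) so that the default cohort
#' reproduces its reference endpoint summaries: Ddx 79 -> 90.7 percent, DxJ
#' 27 -> 46.5 percent, test ordering 46 -> 64.5 percent, cognitive errors
#' 0.87 -> 0.43 per case, misdiagnosis 27 -> 9 percent across 20 cases.
#'
#' @return Named list of calibration constants.
#' @export
vpdx_calibration <- function() {
  list(
    # skill trajectories: logit(t) = a + b * log(t) (+ school + student + AR1)
    a_ddx = 1.2749, b_ddx = 0.3576,
    a_dxj = -1.7153, b_dxj = 0.1968,
    a_inv = 0.3796, b_inv = 0.2096,
    a_err = -2.5327, b_err = -0.1382,
    # verification habit: probability of systematic competitor rule-out
    a_verify = -0.2686, b_verify = 0.2677,
    # correctness link (component scores on the 0-10 point scale);
    # gamma_t carries practice-driven accuracy growth not mediated by the
    # four scored components (knowledge gains), entering as gamma_t * f(t)
    gamma0 = -0.9129,
    gamma_t = 0.1151,
    gamma = c(dxj = 0.29, inv = 0.18, ddx = 0.12, err = 0.42),
    # behavior multipliers on the error-proneness probability q
    mult = c(conf = 0.8, anchor = 0.7, satisfice = 0.4,
             wrong_pair = 0.35, inappropriate = 0.6, reorder = 0.25),
    # variance components
    school_sd = 0.25, student_sd = 0.5, ar_rho = 0.4, ar_sd = 0.35,
    # penalty on ordering tests for diagnoses never entertained
    unconsidered_test_shift = -2
  )
}

#' Configuration for a simulated cohort study
#'
#' @param seed Mandatory integer seed; every random draw derives from it.
#' @param n_schools,n_students_per_school,n_cases Study size. Defaults (5
#'   schools x 200 students x 20 sequenced cases) emulate a multi-site
#'   pre-clerkship cohort of ~1,000 students.
#' @param cohort `"M1"` (default) or `"M2"`. The M2 cohort shares baseline
#'   skills but is less error-prone at baseline (`m2_a_err_shift`) and by
#'   convention completes 10 cases.
#' @param m2_a_err_shift Added to the error-proneness intercept for M2.
#'   The default (-0.9) separates baseline error rates between cohorts
#'   while leaving component-score baselines untouched and keeping the
#'   20-case M1 cohort ahead of the 10-case M2 cohort on end-of-curriculum
#'   error rates.
#' @param learning_shape `"log"` (default, f(t) = log t) or `"linear"`
#'   (f(t) = t - 1).
#' @param calibration Constants from [vpdx_calibration()]; override
#'   individual entries via this argument.
#' @return A list of class `vp_sim_config`.
#' @export
sim_config <- function(seed,
                       n_schools = 5,
                       n_students_per_school = 200,
                       n_cases = 20,
                       cohort = c("M1", "M2"),
                       m2_a_err_shift = -0.9,
                       learning_shape = c("log", "linear"),
                       calibration = vpdx_calibration()) {
  if (missing(seed) || !is.numeric(seed) || is.na(seed)) {
    vpdx_abort("sim_config: seed is mandatory", class = "vpdx_config_error")
  }
  cohort <- match.arg(cohort)
  learning_shape <- match.arg(learning_shape)
  if (n_cases < 1 || n_cases > 20) {
    vpdx_abort("n_cases must be between 1 and 20 (curriculum length)",
               class = "vpdx_config_error")
  }
  cal <- modifyList(vpdx_calibration(), calibration)
  if (cal$ar_rho < 0 || cal$ar_rho >= 1) {
    vpdx_abort("ar_rho must be in [0, 1)", class = "vpdx_config_error")
  }
  if (cal$ar_sd < 0 || cal$student_sd < 0 || cal$school_sd < 0) {
    vpdx_abort("variance components must be non-negative",
               class = "vpdx_config_error")
  }
  structure(list(
    seed = as.integer(seed), n_schools = n_schools,
    n_students_per_school = n_students_per_school, n_cases = n_cases,
    cohort = cohort, m2_a_err_shift = m2_a_err_shift,
    learning_shape = learning_shape, calibration = cal
  ), class = "vp_sim_config")
}

f_learn <- function(t, shape) if (shape == "linear") t - 1 else log(t)

# derived integer seeds stay below 2^31
child_seed <- function(seed, i, salt) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i) + salt) %% 2147483587L) + 1L
}

#' Sample a cohort of learner profiles
#'
#' School effects are drawn once per school (per skill) and added to member
#' students' skill means; each student receives independent skill offsets
#' and a private RNG seed, so enlarging the cohort never perturbs existing
#' students' draws.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per student: ids, cohort, school skill
#'   shifts, student skill offsets and the per-student seed.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "vp_sim_config"))
  cal <- config$calibration
  skills <- c("ddx", "dxj", "inv", "err")
  sch <- lapply(seq_len(config$n_schools), function(s) {
    set.seed(child_seed(config$seed, s, 15485863))
    setNames(rnorm(4, 0, cal$school_sd), paste0("sch_", skills))
  })
  n <- config$n_schools * config$n_students_per_school
  rows <- lapply(seq_len(n), function(i) {
    school <- ((i - 1) %/% config$n_students_per_school) + 1
    set.seed(child_seed(config$seed, i, 32452843))
    u <- rnorm(4, 0, cal$student_sd)
    c(list(
      student_id = sprintf("s%04d", i),
      school_id = sprintf("school%02d", school),
      cohort = config$cohort,
      seed = child_seed(config$seed, i, 49979687)
    ),
    as.list(sch[[school]]),
    setNames(as.list(u), paste0("u_", skills)))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}

# AR(1) stationary residual stream for one student; regenerated from the
# student's private seed so trace t only needs the first t innovations
ar1_residuals <- function(profile_seed, n, rho, sd) {
  set.seed(child_seed(profile_seed, 1, 86028121))
  innov <- rnorm(n)
  e <- numeric(n)
  e[1] <- innov[1]
  if (n > 1) for (t in 2:n) e[t] <- rho * e[t - 1] + sqrt(1 - rho^2) * innov[t]
  e * sd
}

# latent logits for one student at cases 1..n
student_logits <- function(profile, config, n = config$n_cases) {
  cal <- config$calibration
  ft <- f_learn(seq_len(n), config$learning_shape)
  e <- ar1_residuals(profile$seed, n, cal$ar_rho, cal$ar_sd)
  a_err <- cal$a_err + if (profile$cohort == "M2") config$m2_a_err_shift else 0
  list(
    ddx = cal$a_ddx + cal$b_ddx * ft + profile$sch_ddx + profile$u_ddx + e,
    dxj = cal$a_dxj + cal$b_dxj * ft + profile$sch_dxj + profile$u_dxj + e,
    inv = cal$a_inv + cal$b_inv * ft + profile$sch_inv + profile$u_inv + e,
    err = a_err + cal$b_err * ft + profile$sch_err + profile$u_err - e,
    verify = cal$a_verify + cal$b_verify * ft,
    resid = e
  )
}

# rubric geometry the behavioral generator needs, derived from any scorecard
rubric_geometry <- function(scorecard, case) {
  rb <- prepare_rubric(scorecard, case)
  req <- rb$req_df
  is_test <- req$datum_id %in% rb$scorecard$test_labels$test_id
  wrong <- rb$scorecard$dxj_labels[rb$scorecard$dxj_labels$label == "wrong", ,
                                   drop = FALSE]
  competitors <- setdiff(rb$appropriate, rb$correct)
  ro_sets <- lapply(setNames(competitors, competitors), function(dx) {
    list(
      findings = req$datum_id[req$diagnosis == dx &
                                req$label == "required_decrease" & !is_test],
      tests = req$datum_id[req$diagnosis == dx &
                             req$label == "required_decrease" & is_test],
      ruleout_tests = dx_ruleout(rb, dx)$tests
    )
  })
  sup <- dx_support(rb, rb$correct)
  list(
    rb = rb,
    correct = rb$correct,
    competitors = competitors,
    distractors = setdiff(names(case$diagnosis_lexicon), rb$appropriate),
    req = req, req_is_test = is_test,
    wrong_pairs = wrong,
    ro_sets = ro_sets,
    support_data = sup$data,
    support_tests = sup$tests,
    required_tests = rb$required_tests,
    inappropriate_tests = rb$inappropriate_tests,
    test_link_dx = setNames(rb$test_links$diagnosis, rb$test_links$test_id),
    n_req = nrow(req)
  )
}

#' Simulate one student trace for one case
#'
#' Behavior is generated stage-wise: appropriate diagnoses enter the
#' differential with probability `plogis(skill_ddx)`; required
#' justification entries are assigned with probability `plogis(skill_dxj)`
#' (test-result entries only when the test was ordered), with a growing
#' "verification habit" that systematically rules out listed competitors;
#' required tests are ordered with probability `plogis(skill_inv)` (shifted
#' down for diagnoses never entertained); error-prone behaviors
#' (contradiction-as-support, anchoring on an early wrong diagnosis,
#' narrow differentials, inappropriate and duplicate orders) are injected
#' with probabilities proportional to `plogis(skill_err)`. The final
#' diagnosis is correct with probability
#' `plogis(gamma0 + gamma_dxj * dxj + gamma_inv * inv + gamma_ddx * ddx -
#' gamma_err * errors)` on the realized performance.
#'
#' @param profile One row of [sample_cohort()].
#' @param case,scorecard The case and rubric to play.
#' @param sequence_index Position in the student's sequence (>= 1).
#' @param config The [sim_config()].
#' @param geometry Precomputed [rubric_geometry] (internal speed-up).
#' @return A `vp_trace`.
#' @export
simulate_trace <- function(profile, case, scorecard, sequence_index, config,
                           geometry = NULL) {
  stopifnot(sequence_index >= 1)
  g <- geometry %||% rubric_geometry(scorecard, case)
  lg <- student_logits(profile, config, n = max(sequence_index, 1))
  t <- sequence_index
  set.seed(child_seed(profile$seed, t, 67867967))
  cal <- config$calibration
  p_ddx <- plogis(lg$ddx[t]); p_dxj <- plogis(lg$dxj[t])
  p_inv <- plogis(lg$inv[t]); q <- plogis(lg$err[t])
  v <- runif(1) < plogis(lg$verify[t])
  m <- cal$mult

  inj_conf <- runif(1) < m[["conf"]] * q
  inj_anchor <- runif(1) < m[["anchor"]] * q
  inj_sat <- runif(1) < m[["satisfice"]] * q

  # --- differential ----------------------------------------------------------
  listed <- c(g$correct, g$competitors)[c(TRUE, runif(length(g$competitors)) < p_ddx)]
  if (runif(1) > p_ddx) listed <- setdiff(listed, g$correct)
  extra <- g$distractors[runif(length(g$distractors)) < 0.15]
  anchor_dx <- if (inj_anchor && length(g$competitors))
    sample(g$competitors, 1) else NA_character_
  if (!is.na(anchor_dx)) listed <- union(listed, anchor_dx)
  if (length(listed) == 0) listed <- sample(c(g$competitors, g$correct), 1)
  if (inj_sat) {
    keep1 <- if (!is.na(anchor_dx)) anchor_dx else sample(listed, 1)
    listed <- keep1
    extra <- character()
  }
  entries_all <- head(c(listed, extra), 5)

  # leading diagnosis per stage
  lead_early <- if (!is.na(anchor_dx)) anchor_dx else sample(entries_all, 1)
  lead_phys <- if (!is.na(anchor_dx)) anchor_dx
               else if (g$correct %in% entries_all && runif(1) < 0.6) g$correct
               else lead_early

  # --- tests -----------------------------------------------------------------
  p_req <- vapply(g$required_tests, function(tid) {
    dx <- g$test_link_dx[tid]
    considered <- is.na(dx) || dx %in% entries_all
    plogis(lg$inv[t] + if (considered) 0 else cal$unconsidered_test_shift)
  }, numeric(1))
  ordered_req <- g$required_tests[runif(length(g$required_tests)) < p_req]
  ordered_inapp <- g$inappropriate_tests[
    runif(length(g$inappropriate_tests)) < m[["inappropriate"]] * q]
  ordered <- c(ordered_req, ordered_inapp)
  reorder <- length(ordered) > 0 && runif(1) < m[["reorder"]] * q
  orders <- c(ordered, if (reorder) ordered)
  n_rounds <- if (length(orders) == 0) 0L
              else min(length(orders), 1L + rbinom(1, 1, 0.4) + if (reorder) 1L else 0L)
  round_index <- if (length(orders))
    sort(c(seq_len(n_rounds), sample(n_rounds, max(0, length(orders) - n_rounds),
                                     replace = TRUE))) else integer()

  # --- justification assignments --------------------------------------------
  a_datum <- character(); a_dx <- character(); a_dir <- character()
  add <- function(datum, dx, dir) {
    a_datum <<- c(a_datum, datum); a_dx <<- c(a_dx, dx); a_dir <<- c(a_dir, dir)
  }
  for (dx in intersect(g$competitors, entries_all)) {
    ro <- g$ro_sets[[dx]]
    avail <- c(ro$findings, intersect(ro$tests, ordered))
    if (v) {
      for (d in avail) add(d, dx, "decreases")
    } else {
      for (d in avail) if (runif(1) < p_dxj) add(d, dx, "decreases")
    }
  }
  test_ids <- g$rb$scorecard$test_labels$test_id
  sup_avail <- unique(c(setdiff(g$support_data, test_ids),
                        intersect(g$support_data, ordered)))
  for (d in sup_avail) if (runif(1) < p_dxj) add(d, g$correct, "increases")
  # any required entries not covered above (e.g. competitor support in other
  # rubrics) at the base assignment rate, test results only when ordered
  done <- paste(a_datum, a_dx)
  rest <- g$req[!(paste(g$req$datum_id, g$req$diagnosis) %in%
                    c(done, paste(sup_avail, g$correct),
                      unlist(lapply(intersect(g$competitors, entries_all),
                                    function(dx) {
                                      ro <- g$ro_sets[[dx]]
                                      paste(c(ro$findings, ro$tests), dx)
                                    })))), , drop = FALSE]
  for (i in seq_len(nrow(rest))) {
    d <- rest$datum_id[i]
    if (d %in% test_ids && !(d %in% ordered)) next
    if (runif(1) < p_dxj) {
      add(d, rest$diagnosis[i],
          if (rest$label[i] == "required_increase") "increases" else "decreases")
    }
  }
  # specious assignments on rubric-wrong pairs
  wp <- g$wrong_pairs
  for (i in seq_len(nrow(wp))) {
    if (runif(1) < m[["wrong_pair"]] * q) add(wp$datum_id[i], wp$diagnosis[i],
                                              "increases")
  }
  # injected confirmation bias: contradicting datum read as support of the
  # leading diagnosis
  if (inj_conf) {
    ld <- lead_phys
    cand <- unique(c(
      g$req$datum_id[g$req$diagnosis == ld & g$req$label == "required_decrease" &
                       !g$req_is_test],
      wp$datum_id[wp$diagnosis == ld]))
    if (length(cand)) add(sample(cand, 1), ld, "increases")
  }

  # --- realized performance and the correctness link -------------------------
  key_all <- paste(a_datum, a_dx, a_dir)
  dedup <- !duplicated(paste(a_datum, a_dx))
  req_key <- paste(g$req$datum_id, g$req$diagnosis,
                   ifelse(g$req$label == "required_increase", "increases",
                          "decreases"))
  n_credit <- sum(unique(key_all) %in% req_key)
  wrong_key <- paste(wp$datum_id, wp$diagnosis)
  n_bad <- sum(unique(paste(a_datum, a_dx, a_dir)[a_dir == "increases"]) %in%
                 paste(wrong_key, "increases"))
  dxj_pct <- 100 * max(0, n_credit - 0.5 * n_bad) / g$n_req
  inv_pct <- 100 * max(0, length(ordered_req) - length(ordered_inapp)) /
    length(g$required_tests)
  ddx_pct <- 100 * sum(g$rb$appropriate %in% entries_all) /
    length(g$rb$appropriate)

  sup_assigned <- sum(g$support_data %in% a_datum[a_dx == g$correct &
                                                    a_dir == "increases"])
  pc_b <- frac0(sup_assigned, length(g$support_data)) < 0.5 &&
    frac0(length(intersect(g$support_tests, ordered)), length(g$support_tests)) < 0.5
  fr_b <- any(vapply(intersect(g$competitors, entries_all), function(dx) {
    ro <- g$ro_sets[[dx]]
    all_ids <- c(ro$findings, ro$tests)
    got <- sum(all_ids %in% a_datum[a_dx == dx & a_dir == "decreases"])
    frac0(got, length(all_ids)) < 0.5 && !any(ro$ruleout_tests %in% ordered)
  }, logical(1)))
  err_b <- pc_b + fr_b + inj_conf + inj_anchor + inj_sat

  gam <- cal$gamma
  eta <- cal$gamma0 + cal$gamma_t * f_learn(t, config$learning_shape) +
    gam[["dxj"]] * dxj_pct / 10 + gam[["inv"]] * inv_pct / 10 +
    gam[["ddx"]] * ddx_pct / 10 - gam[["err"]] * err_b
  correct <- runif(1) < plogis(eta)

  # --- final diagnosis and snapshots ----------------------------------------
  if (correct) {
    final_dx <- g$correct
  } else if (!is.na(anchor_dx)) {
    final_dx <- anchor_dx
  } else {
    alt <- setdiff(entries_all, g$correct)
    final_dx <- if (length(alt)) sample(alt, 1)
                else sample(c(g$competitors, g$distractors), 1)
  }
  lead_inv <- final_dx
  snap_entries <- function(lead) {
    ent <- unique(c(lead, entries_all))
    if (!correct && lead != g$correct && g$correct %in% ent && runif(1) < 0.5) {
      ent <- unique(c(lead, g$correct, setdiff(ent, c(lead, g$correct))))
    }
    head(ent, 5)
  }
  mk_snap <- function(stage, lead) {
    ent <- snap_entries(lead)
    list(stage = stage, entries = ent, most_probable = ent[1])
  }
  snaps <- list(
    mk_snap("intro", lead_early),
    mk_snap("history", lead_early),
    mk_snap("physical", lead_phys),
    mk_snap("investigations", lead_inv)
  )

  # occasionally enter synonyms rather than canonical labels
  lex <- case$diagnosis_lexicon
  reword <- function(x) {
    vapply(x, function(d) {
      syn <- lex[[d]]
      if (length(syn) && runif(1) < 0.3) sample(syn, 1) else d
    }, character(1))
  }
  snaps <- lapply(snaps, function(s) {
    ent <- reword(s$entries)
    list(stage = s$stage, entries = ent, most_probable = ent[1])
  })
  final_text <- reword(final_dx)[[1]]

  # --- navigation ------------------------------------------------------------
  zsk <- plogis(lg$dxj[t]) - 0.35
  t_hist <- rlnorm(1, log(5.5) + 0.9 * zsk, 0.45)
  t_phys <- rlnorm(1, log(3.2) + 0.9 * zsk, 0.45)
  t_inv <- rlnorm(1, log(4.0), 0.40)
  v_hist <- 1L + rpois(1, 1.2 + 1.5 * max(0, zsk))
  v_phys <- 1L + rpois(1, 1.2 + 1.5 * max(0, zsk))
  v_inv <- 1L + rpois(1, 0.6)
  clock <- 0
  nav_stage <- character(); nav_in <- numeric(); nav_out <- numeric()
  push <- function(stage, minutes) {
    nav_stage <<- c(nav_stage, stage)
    nav_in <<- c(nav_in, clock)
    clock <<- clock + minutes * 60
    nav_out <<- c(nav_out, clock)
  }
  push("intro", 0.3)
  visits <- c(rep("history", v_hist), rep("physical", v_phys),
              rep("investigations", v_inv))
  durs <- c(rep(t_hist / v_hist, v_hist), rep(t_phys / v_phys, v_phys),
            rep(t_inv / v_inv, v_inv))
  first_pass <- match(c("history", "physical", "investigations"), visits)
  ord <- c(first_pass, setdiff(seq_along(visits), first_pass))
  for (k in ord) push(visits[k], durs[k])

  n_a <- length(a_datum)
  vp_trace(
    student_id = profile$student_id, school_id = profile$school_id,
    cohort = profile$cohort, case_id = case$case_id, sequence_index = t,
    ddx_snapshots = snaps,
    dxj_assignments = data.frame(
      datum_id = a_datum, diagnosis = reword(a_dx), direction = a_dir,
      timestamp = if (n_a) seq(60, by = 30, length.out = n_a) else numeric(),
      stringsAsFactors = FALSE),
    test_orders = data.frame(test_text = orders, round_index = round_index,
                             stringsAsFactors = FALSE),
    navigation_events = data.frame(stage = nav_stage, enter_time = nav_in,
                                   exit_time = nav_out, stringsAsFactors = FALSE),
    final_diagnosis = final_text,
    certainty = max(1L, min(5L, 2L + correct + rbinom(1, 2, 0.5))),
    validate = FALSE
  )
}

#' Simulate a full study: all students by all cases
#'
#' @param config A [sim_config()].
#' @param cases,scorecards Lists of cases/rubrics; defaults to
#'   [demo_case_set()] instances of the built-in case. Cases are rotated
#'   across students so case identity is not confounded with sequence
#'   position.
#' @param traces_path Optional JSON-Lines output path.
#' @param truth_path Optional JSON path for the generating-parameter sidecar.
#' @param sequence_indices Which sequence positions to simulate (default all
#'   `1:n_cases`).
#' @return List with `traces` (list of `vp_trace`), `profiles`, and `truth`
#'   (generating parameters incl. per-student latent trajectories).
#' @export
simulate_study <- function(config, cases = NULL, scorecards = NULL,
                           traces_path = NULL, truth_path = NULL,
                           sequence_indices = NULL) {
  stopifnot(inherits(config, "vp_sim_config"))
  if (is.null(cases) || is.null(scorecards)) {
    set <- demo_case_set(config$n_cases)
    cases <- set$cases; scorecards <- set$scorecards
  }
  if (length(cases) < 1) vpdx_abort("need at least one case")
  seq_idx <- sequence_indices %||% seq_len(config$n_cases)
  profiles <- sample_cohort(config)
  geoms <- lapply(seq_along(cases), function(j) {
    rubric_geometry(scorecards[[j]], cases[[j]])
  })
  n_case <- length(cases)
  traces <- vector("list", nrow(profiles) * length(seq_idx))
  k <- 0
  for (i in seq_len(nrow(profiles))) {
    prof <- as.list(profiles[i, ])
    for (t in seq_idx) {
      j <- ((t - 1 + i) %% n_case) + 1   # rotate case order across students
      k <- k + 1
      traces[[k]] <- simulate_trace(prof, cases[[j]], scorecards[[j]], t,
                                    config, geometry = geoms[[j]])
    }
  }
  truth <- list(
    seed = config$seed, cohort = config$cohort,
    n_students = nrow(profiles), n_cases = config$n_cases,
    calibration = config$calibration,
    gamma0 = config$calibration$gamma0,
    gamma = as.list(config$calibration$gamma),
    profiles = profiles,
    ar_rho = config$calibration$ar_rho
  )
  if (!is.null(traces_path)) write_traces(traces, traces_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  list(traces = traces, profiles = profiles, truth = truth)
}

#' Fast score-level cohort generator
#'
#' Draws per-(student, case) component scores, error counts and correctness
#' directly from the same latent-skill trajectories as [simulate_trace()],
#' skipping event-level behavior. The correctness link is exactly logistic
#' in the realized covariates (component scores on the 0-10 point scale and
#' the error count), which makes this generator the reference for
#' parameter-recovery and power studies; its endpoint means track, but do
#' not exactly equal, the trace-level generator's.
#'
#' @param config A [sim_config()].
#' @return A cohort dataset tibble with a `truth` attribute.
#' @export
simulate_cohort_scores <- function(config) {
  stopifnot(inherits(config, "vp_sim_config"))
  cal <- config$calibration
  profiles <- sample_cohort(config)
  n <- nrow(profiles); Tn <- config$n_cases
  ft <- f_learn(seq_len(Tn), config$learning_shape)
  e <- t(vapply(seq_len(n), function(i) {
    ar1_residuals(profiles$seed[i], Tn, cal$ar_rho, cal$ar_sd)
  }, numeric(Tn)))
  if (Tn == 1) e <- matrix(e, ncol = 1)
  lin <- function(a, b, sch, u, sign_e = 1) {
    outer(sch + u, rep(1, Tn)) + matrix(a + b * ft, n, Tn, byrow = TRUE) +
      sign_e * e
  }
  a_err <- cal$a_err + if (config$cohort == "M2") config$m2_a_err_shift else 0
  p_d <- plogis(lin(cal$a_ddx, cal$b_ddx, profiles$sch_ddx, profiles$u_ddx))
  p_j <- plogis(lin(cal$a_dxj, cal$b_dxj, profiles$sch_dxj, profiles$u_dxj))
  p_i <- plogis(lin(cal$a_inv, cal$b_inv, profiles$sch_inv, profiles$u_inv))
  q <- plogis(lin(a_err, cal$b_err, profiles$sch_err, profiles$u_err, -1))
  pv <- plogis(matrix(cal$a_verify + cal$b_verify * ft, n, Tn, byrow = TRUE))
  m <- cal$mult

  set.seed(child_seed(config$seed, 0, 23))
  N <- n * Tn
  rb1 <- function(p) matrix(rbinom(N, 1, pmin(pmax(p, 0), 1)), n, Tn)
  rbk <- function(k, p) matrix(rbinom(N, k, pmin(pmax(p, 0), 1)), n, Tn)

  v <- rb1(pv)
  # geometry constants of the built-in case: 14 required entries (6
  # competitor rule-out findings, 3 rule-out test results, 3 + 2 support),
  # 4 required and 2 inappropriate tests, 4 appropriate diagnoses
  req_ord <- rbk(4, p_i)
  inapp_ord <- rbk(2, m[["inappropriate"]] * q)
  # NB: matrix first -- pmax/pmin take attributes (incl. dim) from arg 1
  inv_pct <- 100 * pmax(req_ord - inapp_ord, 0) / 4
  listed <- pmin(1 + rbk(3, p_d), 4)          # leading dx always listed
  sat <- rb1(m[["satisfice"]] * q)
  listed[sat == 1] <- 1
  ddx_pct <- 100 * listed / 4
  conf <- rb1(m[["conf"]] * q)
  credit <- v * (6 + rbk(3, p_i)) + (1 - v) * rbk(6, p_j)
  credit <- credit + rbk(3, p_j) + rbk(2, p_i * p_j)
  bad <- rbk(5, m[["wrong_pair"]] * q) + conf
  dxj_pct <- 100 * pmax(credit - 0.5 * bad, 0) / 14
  # organic error probabilities (plug-in approximations of the detectors)
  p_pc <- pmin(1, (1 - p_j)^2 * (1 - p_i)^2)
  p_fr <- 1 - (1 - pmin(1, (1 - v) * (1 - p_j^2) * (1 - p_i)))^3
  err_count <- rb1(p_pc) + rb1(p_fr) + conf + rb1(m[["anchor"]] * q) + sat
  gam <- cal$gamma
  eta <- cal$gamma0 + cal$gamma_t * matrix(ft, n, Tn, byrow = TRUE) +
    gam[["dxj"]] * dxj_pct / 10 + gam[["inv"]] * inv_pct / 10 +
    gam[["ddx"]] * ddx_pct / 10 - gam[["err"]] * err_count
  correct <- rb1(plogis(eta)) == 1

  zsk <- p_j - 0.35
  df <- tibble::tibble(
    student_id = rep(profiles$student_id, each = Tn),
    school_id = rep(profiles$school_id, each = Tn),
    cohort = rep(profiles$cohort, each = Tn),
    case_id = sprintf("case%02d", rep(seq_len(Tn), n)),
    sequence_index = rep(seq_len(Tn), n),
    ddx_pct = as.vector(t(ddx_pct)),
    dxj_pct = as.vector(t(dxj_pct)),
    inv_pct = as.vector(t(inv_pct)),
    correct = as.vector(t(correct)),
    final_dx_points = as.numeric(as.vector(t(correct))),
    error_count = as.vector(t(err_count)),
    n_tests = as.vector(t(req_ord + inapp_ord)),
    n_rounds = pmin(as.vector(t(req_ord + inapp_ord)),
                    1 + rbinom(N, 1, 0.4)),
    time_history = rlnorm(N, log(5.5) + 0.9 * as.vector(t(zsk)), 0.45),
    time_physical = rlnorm(N, log(3.2) + 0.9 * as.vector(t(zsk)), 0.45),
    time_investigations = rlnorm(N, log(4), 0.4),
    views_history = 1 + rpois(N, 1.2 + 1.5 * pmax(0, as.vector(t(zsk)))),
    views_physical = 1 + rpois(N, 1.2 + 1.5 * pmax(0, as.vector(t(zsk)))),
    views_investigations = 1 + rpois(N, 0.6)
  )
  out <- as_cohort_dataset(df)
  attr(out, "truth") <- list(
    gamma0 = cal$gamma0, gamma_t = cal$gamma_t, gamma = as.list(cal$gamma),
    ar_rho = cal$ar_rho, learning_shape = config$learning_shape,
    profiles = profiles
  )
  out
}
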