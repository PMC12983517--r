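# Component scorers against hand-computed values and brute-force oracles.

sc <- toy_scorecard()
cs <- toy_case()

test_that("ddx score credits appropriate diagnoses listed anywhere", {
  # 3 of 4 appropriate ever listed -> 75
  tr <- make_trace(snaps4(list(MI, MI, PE, MI), c(PE, AD)))
  expect_equal(score_ddx(tr, sc, cs), 75)
  # all four plus extraneous entries -> still 100
  tr2 <- make_trace(list(snap("history", c(MI, PE, "panic attack")),
                         snap("physical", c(AD, PC, "pneumonia"))))
  expect_equal(score_ddx(tr2, sc, cs), 100)
  # empty differential throughout -> 0, not an error
  expect_equal(score_ddx(empty_trace(), sc, cs), 0)
})

test_that("ddx score equals a set-intersection oracle on random traces", {
  for (seed in 1:25) {
    tr <- random_trace(seed)
    listed_raw <- unique(unlist(lapply(tr$ddx_snapshots, `[[`, "entries")))
    listed <- unique(match_free_text(listed_raw, cs$diagnosis_lexicon))
    oracle <- 100 * length(intersect(sc$appropriate_diagnoses, listed)) /
      length(sc$appropriate_diagnoses)
    expect_equal(score_ddx(tr, sc, cs), oracle, info = seed)
  }
})

test_that("dxj score follows the credit/deduction formula", {
  # 4 required entries; 3 correct, 1 wrong direction, deduction 0.5 -> 62.5
  mini <- vp_scorecard(
    "mini", c("a", "b"), "a",
    dxj_labels = data.frame(
      datum_id = c("f1", "f2", "f3", "f4"), diagnosis = c("a", "a", "b", "b"),
      label = c("required_increase", "required_increase",
                "required_decrease", "required_decrease")),
    test_labels = data.frame(test_id = "t1", label = "required"))
  tr <- make_trace(list(snap("history", "a")),
                   assignments = assign_df(
                     c("f1", "f2", "f3", "f4"), c("a", "a", "b", "b"),
                     c("increases", "increases", "decreases", "increases")),
                   case_id = "mini")
  expect_equal(score_dxj(tr, mini), 100 * (3 - 0.5) / 4)
  # nothing assigned -> 0
  expect_equal(score_dxj(make_trace(list(snap("history", "a")),
                                    case_id = "mini"), mini), 0)
  # everything required assigned correctly -> 100
  tr3 <- make_trace(list(snap("history", "a")),
                    assignments = assign_df(
                      c("f1", "f2", "f3", "f4"), c("a", "a", "b", "b"),
                      c("increases", "increases", "decreases", "decreases")),
                    case_id = "mini")
  expect_equal(score_dxj(tr3, mini), 100)
  # unknown datum id -> validation error
  tr4 <- make_trace(list(snap("history", "a")),
                    assignments = assign_df("nope", "a", "increases"),
                    case_id = "mini")
  expect_error(score_dxj(tr4, mini), "unknown datum",
               class = "vpdx_validation_error")
})

test_that("dxj score matches exhaustive enumeration on small rubrics", {
  # all (n_data x n_dx) rubric sizes up to 4 x 3; for each, every possible
  # assignment set over the labeled pairs is enumerated and scored with an
  # independent arithmetic oracle
  set.seed(99)
  dirs <- c("none", "increases", "decreases")
  for (nd in 2:4) {
    for (nx in 2:3) {
      data_ids <- paste0("f", seq_len(nd))
      dxs <- paste0("d", seq_len(nx))
      grid <- expand.grid(datum_id = data_ids, diagnosis = dxs,
                          stringsAsFactors = FALSE)
      # random labels; keep enumeration tractable by labeling <= 6 pairs
      keep <- sort(sample(nrow(grid), min(6, nrow(grid))))
      labels <- sample(c("required_increase", "required_decrease",
                         "neutral", "wrong"), length(keep), replace = TRUE)
      labels[1] <- "required_increase"
      dl <- data.frame(datum_id = grid$datum_id[keep],
                       diagnosis = grid$diagnosis[keep], label = labels)
      dl$diagnosis[1] <- "d1"
      dl <- dl[!duplicated(paste(dl$datum_id, dl$diagnosis)), ]
      rub <- vp_scorecard("enum", dxs, "d1", dxj_labels = dl,
                          test_labels = data.frame(test_id = character(),
                                                   label = character()))
      n_req <- sum(dl$label %in% c("required_increase", "required_decrease"))
      if (n_req == 0) next
      combos <- expand.grid(rep(list(dirs), nrow(dl)),
                            stringsAsFactors = FALSE)
      for (ci in seq_len(nrow(combos))) {
        act <- unlist(combos[ci, ], use.names = FALSE)
        on <- act != "none"
        if (!any(on)) next
        # independent oracle: per-pair arithmetic from first principles
        credit <- 0; bad <- 0
        for (j in which(on)) {
          lab <- dl$label[j]
          want <- switch(lab, required_increase = "increases",
                         required_decrease = "decreases", NA_character_)
          if (!is.na(want) && act[j] == want) credit <- credit + 1
          else if (lab == "wrong" ||
                   (!is.na(want) && act[j] != want)) bad <- bad + 1
        }
        oracle <- 100 * max(0, credit - 0.5 * bad) / n_req
        tr <- make_trace(list(snap("history", "d1")),
                         assignments = assign_df(dl$datum_id[on],
                                                 dl$diagnosis[on], act[on]),
                         case_id = "enum")
        expect_equal(score_dxj(tr, rub), oracle,
                     info = paste(nd, nx, ci))
      }
    }
  }
})

test_that("investigation score gains required and loses inappropriate", {
  # 3 required; all 3 ordered plus 1 inappropriate -> 100 * 2/3
  mini <- vp_scorecard(
    "mini", c("a", "b"), "a",
    dxj_labels = data.frame(datum_id = "f1", diagnosis = "a",
                            label = "required_increase"),
    test_labels = data.frame(
      test_id = c("t1", "t2", "t3", "t4", "t5"),
      label = c("required", "required", "required", "inappropriate",
                "neutral")))
  tr <- make_trace(list(snap("history", "a")),
                   orders = orders_df(c("t1", "t2", "t3", "t4")),
                   case_id = "mini")
  expect_equal(score_investigations(tr, mini), 100 * 2 / 3)
  # nothing ordered -> 0
  expect_equal(score_investigations(make_trace(list(snap("history", "a")),
                                               case_id = "mini"), mini), 0)
  # exactly the required set -> 100; neutral tests contribute nothing
  tr2 <- make_trace(list(snap("history", "a")),
                    orders = orders_df(c("t1", "t2", "t3", "t5")),
                    case_id = "mini")
  expect_equal(score_investigations(tr2, mini), 100)
})

test_that("final diagnosis credit is full, second-choice, or none", {
  tr1 <- make_trace(snaps4(list(PE, PE, MI, MI), all4), final = "acute mi")
  expect_equal(score_final_dx(tr1, sc, cs), 1)
  # correct diagnosis second in the final differential, most-probable wrong
  tr2 <- make_trace(list(snap("investigations", c(PE, MI, AD))), final = PE)
  expect_equal(score_final_dx(tr2, sc, cs), 0.5)
  # correct diagnosis absent from the final differential
  tr3 <- make_trace(list(snap("investigations", c(PE, AD))), final = PE)
  expect_equal(score_final_dx(tr3, sc, cs), 0)
})

test_that("penalty thresholds use twice the cohort mean, ties unpunished", {
  stats5 <- list(mean_tests = 5, mean_rounds = 2)
  many <- rep(c("troponin", "ecg"), 6)[1:11]
  tr <- make_trace(list(snap("history", MI)),
                   orders = orders_df(many, rep(1, 11)))
  p <- compute_penalties(tr, sc, stats5, cs)
  expect_true(p$excess_tests)   # 11 > 10
  tr10 <- make_trace(list(snap("history", MI)),
                     orders = orders_df(many[1:10], rep(1, 10)))
  expect_false(compute_penalties(tr10, sc, stats5, cs)$excess_tests)
  # ordering required tests and using both results -> no penalties at all
  tr2 <- make_trace(list(snap("history", MI)),
                    assignments = assign_df(c("troponin", "ecg"), c(MI, MI),
                                            c("increases", "increases")),
                    orders = orders_df(c("troponin", "ecg")))
  p2 <- compute_penalties(tr2, sc, stats5, cs)
  expect_equal(p2$total_penalty_points, 0)
  expect_equal(p2$unused_results_count, 0)
  # three ordered, one used -> two unused
  tr3 <- make_trace(list(snap("history", MI)),
                    assignments = assign_df("troponin", MI, "increases"),
                    orders = orders_df(c("troponin", "ecg", "ct chest")))
  expect_equal(compute_penalties(tr3, sc, stats5, cs)$unused_results_count, 2)
  # auto threshold without cohort stats is a configuration error
  expect_error(compute_penalties(tr3, sc, NULL, cs),
               "cohort_stats", class = "vpdx_config_error")
})

test_that("navigation metrics sum interval durations per stage", {
  tr <- flawed_trace()
  m <- compute_navigation_metrics(tr)
  expect_equal(m$time_history, 7)     # 3 + 4 minutes over two visits
  expect_equal(m$views_history, 2)
  expect_equal(m$time_investigations, 4)
  expect_equal(m$views_investigations, 1)
  # unvisited stage -> zero time, zero views
  tr2 <- make_trace(list(snap("history", MI)),
                    nav = data.frame(stage = "history", enter_time = 0,
                                     exit_time = 300))
  m2 <- compute_navigation_metrics(tr2)
  expect_equal(m2$time_investigations, 0)
  expect_equal(m2$views_investigations, 0)
})

test_that("navigation metrics equal an interval-sum oracle on random streams", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(1:8, 1)
    stages <- sample(c("intro", "history", "physical", "investigations"), n,
                     replace = TRUE)
    durs <- runif(n, 10, 900)
    gaps <- runif(n, 0, 60)
    enter <- cumsum(c(0, head(durs + gaps, -1)))
    nav <- data.frame(stage = stages, enter_time = enter,
                      exit_time = enter + durs)
    tr <- make_trace(list(snap("history", MI)), nav = nav)
    m <- compute_navigation_metrics(tr)
    for (st in c("history", "physical", "investigations")) {
      expect_equal(m[[paste0("time_", st)]],
                   sum(durs[stages == st]) / 60, info = rep)
      expect_equal(m[[paste0("views_", st)]], sum(stages == st))
    }
  }
})

test_that("score_case assembles components; perfect and null play bracket it", {
  s <- score_case(perfect_trace(), sc, toy_stats(), cs)
  expect_equal(s$ddx_pct, 100)
  expect_equal(s$dxj_pct, 100)
  expect_equal(s$inv_pct, 100)
  expect_true(s$correct)
  expect_equal(s$error_count, 0)
  expect_equal(s$total_penalty_points, 0)
  s0 <- score_case(empty_trace(), sc, toy_stats(), cs)
  expect_equal(s0$ddx_pct + s0$dxj_pct + s0$inv_pct, 0)
  expect_false(s0$correct)
})

test_that("a scripted flawed trace matches its hand-computed scorecard", {
  s <- score_case(flawed_trace(), sc, toy_stats(), cs)
  # 7 of 14 required correct, 2 bad assignments at 0.5 deduction each
  expect_equal(s$dxj_pct, 100 * (7 - 1) / 14)
  # 2 required ordered - 1 inappropriate, of 4 required
  expect_equal(s$inv_pct, 25)
  # MI and PE ever listed, of 4 appropriate
  expect_equal(s$ddx_pct, 50)
  # wrong most-probable but correct diagnosis listed second
  expect_equal(s$final_dx_points, 0.5)
  expect_false(s$correct)
  # ecg and colonoscopy results never used; colonoscopy inappropriate
  expect_equal(s$unused_results_count, 2)
  expect_equal(s$inappropriate_tests_count, 1)
  expect_equal(s$total_penalty_points, 2 * 0.5 + 1 * 0.5)
  expect_false(s$excess_tests)
  expect_false(s$excess_rounds)
  # one contradiction-as-support on a leading diagnosis, and the chosen
  # (wrong) diagnosis was never confirmed: its CT angiogram was not ordered
  expect_true(s$confirmation_bias)
  expect_true(s$premature_closure)
  expect_equal(s$error_count, 2)
  expect_equal(s$n_tests, 3)
  expect_equal(s$n_rounds, 2)
})

test_that("scoring is deterministic and clamps percents to [0, 100]", {
  for (seed in 1:20) {
    tr <- random_trace(seed)
    s1 <- score_case(tr, sc, toy_stats(), cs)
    s2 <- score_case(tr, sc, toy_stats(), cs)
    expect_identical(unclass(s1), unclass(s2))
    for (v in c("ddx_pct", "dxj_pct", "inv_pct")) {
      expect_gte(s1[[v]], 0)
      expect_lte(s1[[v]], 100)
    }
    expect_equal(s1$error_count,
                 sum(s1$premature_closure, s1$failure_to_rule_out,
                     s1$confirmation_bias, s1$anchoring,
                     s1$search_satisficing))
  }
})

test_that("one extra correct assignment never lowers dxj; one extra
           inappropriate order never raises inv", {
  req <- sc$dxj_labels[sc$dxj_labels$label %in%
                         c("required_increase", "required_decrease"), ]
  for (seed in 1:15) {
    tr <- random_trace(seed)
    base_dxj <- score_dxj(tr, sc, cs)
    # add one not-yet-made correct required assignment
    made <- paste(tr$dxj_assignments$datum_id,
                  match_free_text(tr$dxj_assignments$diagnosis,
                                  cs$diagnosis_lexicon))
    avail <- req[!(paste(req$datum_id, req$diagnosis) %in% made), ]
    if (nrow(avail)) {
      add <- avail[1, ]
      tr2 <- tr
      tr2$dxj_assignments <- rbind(
        tr$dxj_assignments,
        data.frame(datum_id = add$datum_id, diagnosis = add$diagnosis,
                   direction = ifelse(add$label == "required_increase",
                                      "increases", "decreases"),
                   timestamp = 1e6))
      expect_gte(score_dxj(tr2, sc, cs), base_dxj)
    }
    # add one inappropriate test order
    base_inv <- score_investigations(tr, sc, cs)
    tr3 <- tr
    nr <- if (nrow(tr$test_orders)) max(tr$test_orders$round_index) else 0
    tr3$test_orders <- rbind(tr$test_orders,
                             data.frame(test_text = "colonoscopy",
                                        round_index = max(nr, 1)))
    expect_lte(score_investigations(tr3, sc, cs), base_inv)
  }
})

test_that("score_traces computes auto cohort statistics and one row per trace", {
  trs <- list(perfect_trace(), flawed_trace())
  trs[[2]]$student_id <- "s2"
  ds <- score_traces(trs, sc, cs)
  expect_equal(nrow(ds), 2)
  expect_equal(sort(ds$dxj_pct), sort(c(100, 100 * 6 / 14)))
})
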