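# Rule-based detectors: spec'd clause behavior, archetype separability,
# threshold monotonicity.

sc <- toy_scorecard()
cs <- toy_case()

test_that("premature closure needs both low support and missing confirmation", {
  # final diagnosis chosen with nothing assigned and nothing ordered
  tr <- make_trace(snaps4(list(MI, MI, MI, MI), all4), final = MI)
  expect_true(detect_premature_closure(tr, sc, cs)$flag)
  # all supporting data assigned -> not flagged even with no tests
  tr2 <- make_trace(snaps4(list(MI, MI, MI, MI), all4),
                    assignments = support_assignments(), final = MI)
  expect_false(detect_premature_closure(tr2, sc, cs)$flag)
  # fractions exactly at the threshold escape ("< theta", not "<=")
  rub <- vp_scorecard(
    "t", c("a", "b"), "a",
    dxj_labels = data.frame(datum_id = c("f1", "f2", "f3", "f4"),
                            diagnosis = "a", label = "required_increase"),
    test_labels = data.frame(test_id = c("t1", "t2"), label = "required"),
    test_links = data.frame(test_id = c("t1", "t2"), diagnosis = "a",
                            link = "confirms"))
  tr3 <- make_trace(list(snap("investigations", "a")),
                    assignments = assign_df(c("f1", "f2"), c("a", "a"),
                                            c("increases", "increases")),
                    orders = orders_df("t1"), final = "a", case_id = "t")
  expect_false(detect_premature_closure(tr3, rub)$flag)   # 2/4 and 1/2
  # one fewer assignment drops the data fraction below 0.5 -> flagged
  tr4 <- make_trace(list(snap("investigations", "a")),
                    assignments = assign_df("f1", "a", "increases"),
                    orders = orders_df(character()), final = "a",
                    case_id = "t")
  expect_true(detect_premature_closure(tr4, rub)$flag)
})

test_that("failure to rule out targets listed, unexcluded competitors", {
  # competitor listed, none of its rule-out data assigned, no test ordered
  tr <- make_trace(snaps4(list(MI, MI, MI, MI), c(MI, PC)),
                   assignments = support_assignments(), final = MI)
  r <- detect_failure_to_rule_out(tr, sc, cs)
  expect_true(r$flag)
  expect_match(r$evidence[1], "pericarditis")
  # every listed competitor ruled out -> not flagged
  tr2 <- make_trace(snaps4(list(MI, MI, MI, MI), all4),
                    assignments = rbind(support_assignments(),
                                        ruleout_assignments()), final = MI)
  expect_false(detect_failure_to_rule_out(tr2, sc, cs)$flag)
  # a competitor never listed is the Ddx score's concern, not this flag's
  tr3 <- make_trace(snaps4(list(MI, MI, MI, MI), MI),
                    assignments = support_assignments(), final = MI)
  expect_false(detect_failure_to_rule_out(tr3, sc, cs)$flag)
  # ordering the discriminating test excuses sparse rule-out assignments
  tr4 <- make_trace(snaps4(list(MI, MI, MI, MI), c(MI, PC)),
                    assignments = support_assignments(),
                    orders = orders_df("cardiac echo"), final = MI)
  expect_false(detect_failure_to_rule_out(tr4, sc, cs)$flag)
})

test_that("confirmation bias counts contradictions read as support of a
           leading diagnosis", {
  # contradicting datum marked as increasing the leading diagnosis
  tr <- make_trace(snaps4(list(PC, PC, PC, PC), all4),
                   assignments = assign_df("h2", PC, "increases"), final = PC)
  expect_true(detect_confirmation_bias(tr, sc, cs)$flag)
  # assignments all agree with the rubric -> no flag
  tr2 <- perfect_trace()
  expect_false(detect_confirmation_bias(tr2, sc, cs)$flag)
  # same contradiction on a diagnosis that was never leading -> no flag
  tr3 <- make_trace(snaps4(list(MI, MI, MI, MI), all4),
                    assignments = assign_df("h2", PC, "increases"), final = MI)
  expect_false(detect_confirmation_bias(tr3, sc, cs)$flag)
})

test_that("anchoring needs persistence, revealed contradictions, and a
           matching wrong final diagnosis", {
  # wrong diagnosis held from intro to final despite revealed contradictions
  tr <- archetype_trace("anchoring")
  r <- detect_anchoring(tr, sc, cs)
  expect_true(r$flag)
  expect_match(r$evidence[1], "pericarditis")
  # revising the leading diagnosis at the end -> no flag
  expect_false(detect_anchoring(corrected_twin("anchoring"), sc, cs)$flag)
  # only one contradicting datum exists (default threshold needs 2)
  rub1 <- vp_scorecard(
    "t", c("a", "b"), "a",
    dxj_labels = data.frame(
      datum_id = c("f1", "f2"), diagnosis = c("a", "b"),
      label = c("required_increase", "required_decrease")),
    test_labels = data.frame(test_id = "t1", label = "required"))
  c1 <- vp_case("t", "intro",
                findings = data.frame(finding_id = c("f1", "f2"),
                                      stage = "history",
                                      text = c("x", "y")),
                tests = data.frame(test_id = "t1", name = "t1",
                                   synonyms = I(list("test one")),
                                   result = "r"),
                correct_diagnosis = "a",
                diagnosis_lexicon = list(a = "dx a", b = "dx b"))
  trb <- make_trace(snaps4(list("b", "b", "b", "b"), c("a", "b")),
                    final = "b", case_id = "t")
  expect_false(detect_anchoring(trb, rub1, c1)$flag)
  expect_true(detect_anchoring(
    trb, rub1, c1,
    thresholds = error_thresholds(anchor_min_contradictions = 1))$flag)
})

test_that("search satisficing needs a narrow differential and poor coverage", {
  tr <- archetype_trace("search_satisficing")
  expect_true(detect_search_satisficing(tr, sc, cs)$flag)
  # five-entry differential covering all appropriate diagnoses
  expect_false(detect_search_satisficing(perfect_trace(), sc, cs)$flag)
  # narrow list but good coverage across stages -> second clause fails
  tr3 <- make_trace(list(snap("history", c(MI, PE)),
                         snap("physical", c(AD, MI)),
                         snap("investigations", c(MI, PC))), final = MI)
  expect_false(detect_search_satisficing(tr3, sc, cs)$flag)
})

test_that("each archetype trips exactly its own detector and corrected
           twins trip none", {
  flags <- sapply(ERROR_NAMES, function(a) {
    r <- detect_all(archetype_trace(a), sc, cs)
    unlist(r[ERROR_NAMES])
  })
  expect_equal(unname(flags), diag(5) == 1)
  for (a in ERROR_NAMES) {
    r <- detect_all(corrected_twin(a), sc, cs)
    expect_equal(r$error_count, 0, info = a)
  }
})

test_that("every raised flag carries non-empty evidence", {
  for (a in ERROR_NAMES) {
    r <- detect_all(archetype_trace(a), sc, cs)
    expect_gt(length(r$evidence[[a]]), 0, label = a)
  }
  for (seed in 1:15) {
    r <- detect_all(random_trace(seed), sc, cs)
    for (a in ERROR_NAMES) {
      if (isTRUE(r[[a]])) expect_gt(length(r$evidence[[a]]), 0)
    }
    expect_equal(r$error_count, sum(unlist(r[ERROR_NAMES])))
  }
})

test_that("raising confirmation/rule-out thresholds never lowers flag rates", {
  lo <- error_thresholds(confirm_fraction = 0.3, ruleout_fraction = 0.3)
  hi <- error_thresholds(confirm_fraction = 0.8, ruleout_fraction = 0.8)
  for (seed in 1:20) {
    tr <- random_trace(seed)
    if (!nzchar(tr$final_diagnosis)) next
    pc_lo <- detect_premature_closure(tr, sc, cs, thresholds = lo)$flag
    pc_hi <- detect_premature_closure(tr, sc, cs, thresholds = hi)$flag
    expect_true(!pc_lo || pc_hi, info = seed)
    fr_lo <- detect_failure_to_rule_out(tr, sc, cs, thresholds = lo)$flag
    fr_hi <- detect_failure_to_rule_out(tr, sc, cs, thresholds = hi)$flag
    expect_true(!fr_lo || fr_hi, info = seed)
  }
})

test_that("three DxJ-based detectors ignore navigation and round structure", {
  for (seed in 1:10) {
    tr <- random_trace(seed)
    r1 <- detect_all(tr, sc, cs)
    tr2 <- tr
    tr2$navigation_events <- nav_df()
    if (nrow(tr2$test_orders)) tr2$test_orders$round_index <- 1L
    r2 <- detect_all(tr2, sc, cs)
    expect_identical(unlist(r1[ERROR_NAMES]), unlist(r2[ERROR_NAMES]))
  }
})

test_that("detector thresholds validate their ranges", {
  expect_error(error_thresholds(confirm_fraction = 0), "confirm_fraction",
               class = "vpdx_validation_error")
  expect_error(error_thresholds(ruleout_fraction = 1.2), "ruleout_fraction",
               class = "vpdx_validation_error")
  expect_error(error_thresholds(satisfice_min_ddx = 0), ">= 1",
               class = "vpdx_validation_error")
})
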