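# Shared fixtures: the toy chest-pain case, hand-scripted traces (perfect,
# flawed, archetypes for each cognitive error plus corrected twins), and
# small builders. All fixtures are built in code.

MI <- "acute myocardial infarction"
PE <- "pulmonary embolism"
AD <- "aortic dissection"
PC <- "acute pericarditis"

toy_case <- function() demo_case("toy_mi")
toy_scorecard <- function() demo_scorecard("toy_mi")

toy_stats <- function() list(mean_tests = 4, mean_rounds = 2)

snap <- function(stage, entries) {
  list(stage = stage, entries = entries,
       most_probable = if (length(entries)) entries[[1]] else NULL)
}

# four-stage snapshot list from per-stage leading dx + shared tail entries
snaps4 <- function(leads, others = character()) {
  stages <- c("intro", "history", "physical", "investigations")
  lapply(seq_along(stages), function(i) {
    ent <- head(unique(c(leads[[i]], others)), 5)
    snap(stages[i], ent)
  })
}

assign_df <- function(datum = character(), dx = character(),
                      dir = character()) {
  data.frame(datum_id = datum, diagnosis = dx, direction = dir,
             timestamp = seq_len(length(datum)) * 10,
             stringsAsFactors = FALSE)
}

orders_df <- function(tests = character(), rounds = rep(1L, length(tests))) {
  data.frame(test_text = tests, round_index = as.integer(rounds),
             stringsAsFactors = FALSE)
}

nav_df <- function() {
  data.frame(stage = c("intro", "history", "physical", "investigations"),
             enter_time = c(0, 60, 500, 900),
             exit_time = c(60, 480, 880, 1400), stringsAsFactors = FALSE)
}

make_trace <- function(snapshots, assignments = assign_df(),
                       orders = orders_df(), nav = nav_df(),
                       final = MI, certainty = 4L, student = "s1",
                       case_id = "toy_mi", seqi = 1L) {
  vp_trace(student_id = student, school_id = "school01", cohort = "M1",
           case_id = case_id, sequence_index = seqi,
           ddx_snapshots = snapshots, dxj_assignments = assignments,
           test_orders = orders, navigation_events = nav,
           final_diagnosis = final, certainty = certainty)
}

all4 <- c(MI, PE, AD, PC)

# every required entry assigned with the rubric direction, all required
# tests ordered, final diagnosis correct
perfect_trace <- function() {
  sc <- toy_scorecard()
  req <- sc$dxj_labels[sc$dxj_labels$label %in%
                         c("required_increase", "required_decrease"), ]
  make_trace(
    snaps4(list(MI, MI, MI, MI), all4),
    assignments = assign_df(req$datum_id, req$diagnosis,
                            ifelse(req$label == "required_increase",
                                   "increases", "decreases")),
    orders = orders_df(c("troponin", "ekg", "ct chest", "cardiac echo"),
                       c(1, 1, 1, 2)),
    final = "heart attack", certainty = 5L
  )
}

empty_trace <- function() {
  make_trace(
    snapshots = list(),
    nav = data.frame(stage = character(), enter_time = numeric(),
                     exit_time = numeric(), stringsAsFactors = FALSE),
    final = "", certainty = 1L
  )
}

# scripted flawed trace with hand-computed component scores (see
# test-scoring.R for the arithmetic)
flawed_trace <- function() {
  make_trace(
    snaps4(list(MI, MI, MI, PE), c(MI, PE)),
    assignments = assign_df(
      c("h1", "h3", "p2", "h4", "troponin", "h5", "p1", "h1", "h2"),
      c(MI, MI, MI, PE, MI, AD, AD, PC, PE),
      c("increases", "increases", "increases", "decreases", "increases",
        "decreases", "decreases", "increases", "increases")),
    orders = orders_df(c("troponin", "ecg", "colonoscopy"), c(1, 1, 2)),
    nav = data.frame(
      stage = c("intro", "history", "physical", "investigations", "history"),
      enter_time = c(0, 30, 250, 420, 700),
      exit_time = c(30, 210, 400, 660, 940), stringsAsFactors = FALSE),
    final = PE
  )
}

# competitor rule-out assignments (finding-level, >= half of each rule-out
# set) for all three competitors
ruleout_assignments <- function() {
  assign_df(c("h2", "h4", "h5", "p1", "h2", "p3"),
            c(PE, PE, AD, AD, PC, PC),
            rep("decreases", 6))
}

support_assignments <- function() {
  assign_df(c("h1", "h3", "p2"), rep(MI, 3), rep("increases", 3))
}

# archetype traces: each trips exactly one detector; corrected twins trip none
archetype_trace <- function(which) {
  switch(which,
    premature_closure = make_trace(
      snaps4(list(MI, MI, MI, MI), all4),
      assignments = ruleout_assignments(),
      final = MI),
    failure_to_rule_out = make_trace(
      snaps4(list(MI, MI, MI, MI), all4),
      assignments = rbind(support_assignments(),
                          assign_df(c("troponin", "ecg"), c(MI, MI),
                                    c("increases", "increases"))),
      orders = orders_df(c("troponin", "ecg")),
      final = MI),
    confirmation_bias = make_trace(
      snaps4(list(MI, MI, MI, MI), all4),
      assignments = rbind(support_assignments(), ruleout_assignments(),
                          assign_df("p3", MI, "increases")),
      orders = orders_df(c("troponin", "ecg")),
      final = MI),
    anchoring = make_trace(
      snaps4(list(PC, PC, PC, PC), all4),
      assignments = assign_df(c("h2", "h4", "h5", "p1"),
                              c(PE, PE, AD, AD), rep("decreases", 4)),
      # orders the echo (confirming their chosen pericarditis), so the flag
      # isolates the anchoring behavior, not premature closure
      orders = orders_df("cardiac echo"),
      final = PC),
    search_satisficing = make_trace(
      list(snap("intro", PC), snap("history", PC), snap("physical", PC),
           snap("investigations", "panic attack")),
      assignments = assign_df(c("h2", "p3"), c(PC, PC), rep("decreases", 2)),
      final = "panic attack")
  )
}

corrected_twin <- function(which) {
  switch(which,
    premature_closure = make_trace(
      snaps4(list(MI, MI, MI, MI), all4),
      assignments = rbind(ruleout_assignments(), support_assignments()),
      final = MI),
    failure_to_rule_out = make_trace(
      snaps4(list(MI, MI, MI, MI), all4),
      assignments = rbind(support_assignments(), ruleout_assignments()),
      orders = orders_df(c("troponin", "ecg")),
      final = MI),
    confirmation_bias = make_trace(
      snaps4(list(MI, MI, MI, MI), all4),
      assignments = rbind(support_assignments(), ruleout_assignments()),
      orders = orders_df(c("troponin", "ecg")),
      final = MI),
    anchoring = make_trace(
      snaps4(list(PC, PC, PC, MI), all4),
      assignments = rbind(support_assignments(), ruleout_assignments()),
      final = MI),
    search_satisficing = perfect_trace()
  )
}

ERROR_NAMES <- c("premature_closure", "failure_to_rule_out",
                 "confirmation_bias", "anchoring", "search_satisficing")

# random valid trace against the toy rubric, for property-style tests
random_trace <- function(seed) {
  set.seed(seed)
  cs <- toy_case()
  dx_pool <- names(cs$diagnosis_lexicon)
  n_snap_entries <- function() sample(0:5, 1)
  stages <- c("intro", "history", "physical", "investigations")
  snaps <- lapply(stages, function(st) {
    ent <- sample(dx_pool, n_snap_entries())
    snap(st, ent)
  })
  pairs <- expand.grid(datum = c(cs$findings$finding_id, cs$tests$test_id),
                       dx = dx_pool, stringsAsFactors = FALSE)
  k <- sample(0:12, 1)
  sel <- pairs[sample(nrow(pairs), k), ]
  n_ord <- sample(0:6, 1)
  ords <- sample(cs$tests$test_id, n_ord)
  make_trace(
    snaps,
    assignments = assign_df(sel$datum, sel$dx,
                            sample(c("increases", "decreases"), k,
                                   replace = TRUE)),
    orders = if (n_ord)
      orders_df(ords, sort(((seq_len(n_ord) - 1) %%
                              sample(seq_len(min(3, n_ord)), 1)) + 1))
      else orders_df(),
    final = sample(c(dx_pool, ""), 1)
  )
}
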