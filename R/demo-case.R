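# A compact built-in chest-pain case and rubric. This is the structural
# template the cohort simulator instantiates (the clinical content itself is
# illustrative): 4 appropriate diagnoses, 8 findings, 6 tests, and a full
# justification label map including test-result data.

DEMO_DX <- c(
  mi = "acute myocardial infarction",
  pe = "pulmonary embolism",
  ad = "aortic dissection",
  pc = "acute pericarditis"
)
DEMO_DISTRACTORS <- c("panic attack", "pneumonia")

#' Built-in demonstration case and scorecard
#'
#' A single staged chest-pain encounter with four appropriate diagnoses
#' (acute myocardial infarction is correct), eight findings and six
#' orderable tests. `demo_case()`/`demo_scorecard()` return one instance;
#' `demo_case_set(n)` replicates the structure under distinct case ids
#' (`case01`, `case02`, ...) for multi-case simulations.
#'
#' @param case_id Case identifier.
#' @return A `vp_case` / `vp_scorecard`; `demo_case_set()` returns
#'   `list(cases =, scorecards =)`.
#' @export
demo_case <- function(case_id = "toy_mi") {
  findings <- data.frame(
    finding_id = c("h1", "h2", "h3", "h4", "h5", "p1", "p2", "p3"),
    stage = c(rep("history", 5), rep("physical", 3)),
    text = c(
      "crushing substernal chest pain radiating to the left arm",
      "no pleuritic or positional component to the pain",
      "diaphoresis and nausea with exertional onset",
      "no history of leg swelling or immobilization",
      "no tearing pain radiating to the back",
      "blood pressure equal in both arms",
      "S4 gallop, patient sweaty and distressed",
      "no pericardial friction rub"
    ),
    stringsAsFactors = FALSE
  )
  tests <- data.frame(
    test_id = c("troponin", "ecg", "ct_angio", "echo", "abdo_us", "colonoscopy"),
    name = c("troponin", "12-lead ECG", "CT angiogram chest",
             "echocardiogram", "abdominal ultrasound", "colonoscopy"),
    result = c(
      "troponin I markedly elevated",
      "ST elevation in anterior leads",
      "no pulmonary embolus; aorta normal calibre",
      "no pericardial effusion; anterior wall hypokinesis",
      "unremarkable",
      "unremarkable"
    ),
    stringsAsFactors = FALSE
  )
  tests$synonyms <- list(
    c("trop", "troponin i", "cardiac enzymes"),
    c("ekg", "electrocardiogram", "12 lead ecg"),
    c("ct chest", "ctpa", "ct pulmonary angiogram", "ct aorta"),
    c("cardiac echo", "transthoracic echo", "tte"),
    c("abdominal us", "ultrasound abdomen"),
    c("scope", "lower endoscopy")
  )
  lex <- list(
    "acute myocardial infarction" = c("myocardial infarction", "heart attack",
                                      "mi", "stemi", "acute mi"),
    "pulmonary embolism" = c("pe", "lung clot", "pulmonary embolus"),
    "aortic dissection" = c("dissection", "dissecting aneurysm",
                            "thoracic aortic dissection"),
    "acute pericarditis" = c("pericarditis"),
    "panic attack" = c("anxiety attack", "panic disorder"),
    "pneumonia" = c("community acquired pneumonia", "cap")
  )
  vp_case(
    case_id = case_id,
    intro = "A 58-year-old presents with sudden severe chest pain.",
    findings = findings,
    tests = tests,
    correct_diagnosis = unname(DEMO_DX["mi"]),
    diagnosis_lexicon = lex
  )
}

#' @rdname demo_case
#' @export
demo_scorecard <- function(case_id = "toy_mi") {
  mi <- DEMO_DX[["mi"]]; pe <- DEMO_DX[["pe"]]
  ad <- DEMO_DX[["ad"]]; pc <- DEMO_DX[["pc"]]
  dxj <- rbind(
    # finding-level justification
    data.frame(datum_id = c("h1", "h3", "p2"), diagnosis = mi,
               label = "required_increase"),
    data.frame(datum_id = c("h2", "h4"), diagnosis = pe,
               label = "required_decrease"),
    data.frame(datum_id = c("h5", "p1"), diagnosis = ad,
               label = "required_decrease"),
    data.frame(datum_id = c("h2", "p3"), diagnosis = pc,
               label = "required_decrease"),
    # test-result justification
    data.frame(datum_id = c("troponin", "ecg"), diagnosis = mi,
               label = "required_increase"),
    data.frame(datum_id = "ct_angio", diagnosis = c(pe, ad),
               label = "required_decrease"),
    data.frame(datum_id = "echo", diagnosis = pc,
               label = "required_decrease"),
    # specious interpretations the rubric explicitly marks wrong
    data.frame(datum_id = c("h1", "h3", "troponin", "p3", "h2"),
               diagnosis = c(pc, pe, pe, mi, ad),
               label = "wrong"),
    # explicit neutral pair (no credit, no deduction)
    data.frame(datum_id = "h4", diagnosis = pc, label = "neutral")
  )
  test_labels <- data.frame(
    test_id = c("troponin", "ecg", "ct_angio", "echo", "abdo_us", "colonoscopy"),
    label = c("required", "required", "required", "required",
              "inappropriate", "inappropriate"),
    stringsAsFactors = FALSE
  )
  # the discriminating tests cut both ways: a positive result confirms the
  # competitor, a negative rules it out
  test_links <- data.frame(
    test_id = c("troponin", "ecg", "ct_angio", "ct_angio", "echo",
                "ct_angio", "ct_angio", "echo"),
    diagnosis = c(mi, mi, pe, ad, pc, pe, ad, pc),
    link = c("confirms", "confirms", "rules_out", "rules_out", "rules_out",
             "confirms", "confirms", "confirms"),
    stringsAsFactors = FALSE
  )
  vp_scorecard(
    case_id = case_id,
    appropriate_diagnoses = unname(DEMO_DX),
    correct_diagnosis = mi,
    dxj_labels = dxj,
    test_labels = test_labels,
    test_links = test_links
  )
}

#' @rdname demo_case
#' @param n Number of case instances.
#' @export
demo_case_set <- function(n = 20) {
  ids <- sprintf("case%02d", seq_len(n))
  list(
    cases = lapply(ids, demo_case),
    scorecards = lapply(ids, demo_scorecard)
  )
}
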