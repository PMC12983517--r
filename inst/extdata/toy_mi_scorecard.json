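{"case_id":"toy_mi","appropriate_diagnoses":["acute myocardial infarction","pulmonary embolism","aortic dissection","acute pericarditis"],"correct_diagnosis":"acute myocardial infarction","dxj_labels":[{"datum_id":"h1","diagnosis":"acute myocardial infarction","label":"required_increase"},{"datum_id":"h3","diagnosis":"acute myocardial infarction","label":"required_increase"},{"datum_id":"p2","diagnosis":"acute myocardial infarction","label":"required_increase"},{"datum_id":"h2","diagnosis":"pulmonary embolism","label":"required_decrease"},{"datum_id":"h4","diagnosis":"pulmonary embolism","label":"required_decrease"},{"datum_id":"h5","diagnosis":"aortic dissection","label":"required_decrease"},{"datum_id":"p1","diagnosis":"aortic dissection","label":"required_decrease"},{"datum_id":"h2","diagnosis":"acute pericarditis","label":"required_decrease"},{"datum_id":"p3","diagnosis":"acute pericarditis","label":"required_decrease"},{"datum_id":"troponin","diagnosis":"acute myocardial infarction","label":"required_increase"},{"datum_id":"ecg","diagnosis":"acute myocardial infarction","label":"required_increase"},{"datum_id":"ct_angio","diagnosis":"pulmonary embolism","label":"required_decrease"},{"datum_id":"ct_angio","diagnosis":"aortic dissection","label":"required_decrease"},{"datum_id":"echo","diagnosis":"acute pericarditis","label":"required_decrease"},{"datum_id":"h1","diagnosis":"acute pericarditis","label":"wrong"},{"datum_id":"h3","diagnosis":"pulmonary embolism","label":"wrong"},{"datum_id":"troponin","diagnosis":"pulmonary embolism","label":"wrong"},{"datum_id":"p3","diagnosis":"acute myocardial infarction","label":"wrong"},{"datum_id":"h2","diagnosis":"aortic dissection","label":"wrong"},{"datum_id":"h4","diagnosis":"acute pericarditis","label":"neutral"}],"test_labels":[{"test_id":"troponin","label":"required"},{"test_id":"ecg","label":"required"},{"test_id":"ct_angio","label":"required"},{"test_id":"echo","label":"required"},{"test_id":"abdo_us","label":"inappropriate"},{"test_id":"colonoscopy","label":"inappropriate"}],"test_links":[{"test_id":"troponin","diagnosis":"acute myocardial infarction","link":"confirms"},{"test_id":"ecg","diagnosis":"acute myocardial infarction","link":"confirms"},{"test_id":"ct_angio","diagnosis":"pulmonary embolism","link":"rules_out"},{"test_id":"ct_angio","diagnosis":"aortic dissection","link":"rules_out"},{"test_id":"echo","diagnosis":"acute pericarditis","link":"rules_out"}],"second_choice_credit":0.5,"wrong_assignment_deduction":0.5,"max_tests_threshold":"auto","max_rounds_threshold":"auto","penalty_weights":{"excess_tests":1,"excess_rounds":1,"unused_result":0.5,"inappropriate_test":0.5}}
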