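{"case_id":"toy_mi","intro":"A 58-year-old presents with sudden severe chest pain.","findings":[{"finding_id":"h1","stage":"history","text":"crushing substernal chest pain radiating to the left arm"},{"finding_id":"h2","stage":"history","text":"no pleuritic or positional component to the pain"},{"finding_id":"h3","stage":"history","text":"diaphoresis and nausea with exertional onset"},{"finding_id":"h4","stage":"history","text":"no history of leg swelling or immobilization"},{"finding_id":"h5","stage":"history","text":"no tearing pain radiating to the back"},{"finding_id":"p1","stage":"physical","text":"blood pressure equal in both arms"},{"finding_id":"p2","stage":"physical","text":"S4 gallop, patient sweaty and distressed"},{"finding_id":"p3","stage":"physical","text":"no pericardial friction rub"}],"tests":[{"test_id":"troponin","name":"troponin","result":"troponin I markedly elevated","synonyms":["trop","troponin i","cardiac enzymes"]},{"test_id":"ecg","name":"12-lead ECG","result":"ST elevation in anterior leads","synonyms":["ekg","electrocardiogram","12 lead ecg"]},{"test_id":"ct_angio","name":"CT angiogram chest","result":"no pulmonary embolus; aorta normal calibre","synonyms":["ct chest","ctpa","ct pulmonary angiogram","ct aorta"]},{"test_id":"echo","name":"echocardiogram","result":"no pericardial effusion; anterior wall hypokinesis","synonyms":["cardiac echo","transthoracic echo","tte"]},{"test_id":"abdo_us","name":"abdominal ultrasound","result":"unremarkable","synonyms":["abdominal us","ultrasound abdomen"]},{"test_id":"colonoscopy","name":"colonoscopy","result":"unremarkable","synonyms":["scope","lower endoscopy"]}],"correct_diagnosis":"acute myocardial infarction","diagnosis_lexicon":{"acute myocardial infarction":["myocardial infarction","heart attack","mi","stemi","acute mi"],"pulmonary embolism":["pe","lung clot","pulmonary embolus"],"aortic dissection":["dissection","dissecting aneurysm","thoracic aortic dissection"],"acute pericarditis":"pericarditis","panic attack":["anxiety attack","panic disorder"],"pneumonia":["community acquired pneumonia","cap"]}}
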