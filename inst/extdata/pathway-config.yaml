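# Default pathway configuration: NICE-style diagnostic thresholds, the
# inpatient reminder policy, the guideline recommendation knowledge base,
# and ward-to-clinician routing. Every value here is a tunable; edit a copy
# of this file and pass it via --config or load_pathway_config().

thresholds:
  pre_diabetes_min: 42    # mmol/mol; non-diabetic hyperglycaemia from here
  diabetes_min: 48        # mmol/mol; diabetes diagnostic cut-off
  severe_min: 86          # mmol/mol (~10%); severe dysglycaemia / decompensation
  red_flag_min: 42        # results at/above this render in red

reminder_policy:
  first_reminder_after_days: 4
  reminder_interval_days: 7
  evaluation_time_of_day: "09:00"

history_limit: 10
red_flag_marker: "** RAISED **"
nhs_check: warn

knowledge_base:
  reminder:
    - category: MONITORING
      text: >-
        No HbA1c result has been reported for this patient since admission.
        Please arrange HbA1c testing as part of routine physical health
        screening for inpatients.
    - category: LINKS
      text: >-
        Physical health screening guidance is available on the Trust staff
        intranet.
  NORMAL:
    - category: MONITORING
      text: >-
        HbA1c is within the normal range. Continue routine monitoring;
        repeat HbA1c if clinically indicated or at the next annual physical
        health review.
    - category: LIFESTYLE
      text: >-
        Reinforce healthy lifestyle advice regarding exercise, diet and
        smoking cessation.
    - category: LINKS
      text: >-
        Links to relevant clinical guidelines and medicines information are
        available on the Trust staff intranet.
  PRE_DIABETES:
    - category: MONITORING
      text: >-
        HbA1c meets the threshold for pre-diabetes (non-diabetic
        hyperglycaemia). Review previous results and check whether the
        patient has a known history of diabetes, as a well-controlled
        history will not be evident from the HbA1c level alone.
    - category: LIFESTYLE
      text: >-
        Offer guideline-based lifestyle interventions: advice regarding
        exercise, diet and smoking cessation.
    - category: SCREENING
      text: >-
        Consider cardiovascular risk screening and repeat HbA1c within 3
        months to assess trajectory.
    - category: PHARMACOLOGICAL
      text: >-
        Review current antipsychotic medication; consider antipsychotics
        with lower risk of dysglycaemia where clinically appropriate.
    - category: LINKS
      text: >-
        Links to relevant clinical guidelines and medicines information are
        available on the Trust staff intranet.
  DIABETES:
    - category: MONITORING
      text: >-
        HbA1c meets the diagnostic threshold for diabetes. Review previous
        results and establish whether this is a new diagnosis or known
        diabetes, as a well-controlled history will not be evident from the
        HbA1c level alone.
    - category: LIFESTYLE
      text: >-
        Offer guideline-based lifestyle interventions: advice regarding
        exercise, diet and smoking cessation.
    - category: SCREENING
      text: >-
        Arrange guideline-based screening where indicated, such as foot
        review and eye examination.
    - category: PHARMACOLOGICAL
      text: >-
        For a new diagnosis, initiate appropriate first-line diabetes
        medication per guideline. Consider antipsychotics with lower risk
        of dysglycaemia. Discuss with the specialist diabetes team where
        control is uncertain.
    - category: LINKS
      text: >-
        Links to relevant clinical guidelines and medicines information are
        available on the Trust staff intranet.
  SEVERE_DYSGLYCAEMIA:
    - category: REFERRAL
      text: >-
        HbA1c indicates severe, decompensated dysglycaemia. Urgent referral
        to specialists in decompensated (severely poorly controlled)
        diabetes is indicated.
    - category: MONITORING
      text: >-
        Review previous HbA1c results and the patient's diabetes history;
        monitor closely while specialist input is arranged.
    - category: SCREENING
      text: >-
        Arrange guideline-based screening where indicated, such as foot
        review and eye examination, once acute management is in place.
    - category: PHARMACOLOGICAL
      text: >-
        Review current medication with the specialist diabetes team,
        including antipsychotics with lower risk of dysglycaemia.
    - category: LINKS
      text: >-
        Links to relevant clinical guidelines and medicines information are
        available on the Trust staff intranet.
  known_diabetes_extra:
    - category: PHARMACOLOGICAL
      text: >-
        Known diabetes: consider how to approach intensification of
        medication to manage worsening glycaemic control, in discussion
        with the specialist diabetes team.

routing:
  wards:
    WARD_X:
      - ward.x.clinician1@example.nhs.uk
      - ward.x.clinician2@example.nhs.uk
    WARD_Y:
      - ward.y.clinician1@example.nhs.uk
    WARD_Z:
      - ward.z.clinician1@example.nhs.uk
      - ward.z.clinician2@example.nhs.uk
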