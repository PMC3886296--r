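# Default scenario-space configuration ("round2-default"):
# iron deficiency management in inflammatory bowel disease, second rating
# round structure.  NAID = non-anaemic iron deficiency, IDA = iron
# deficiency anaemia.  Haemoglobin bands in g/dL, upper-exclusive.
version: round2-default
populations:
  NAID:
    variables:
      - name: prev_treatment
        label: Previous treatment of iron deficiency
        levels:
          - none
          - oral_success
          - oral_failure
          - iv_low_success
          - iv_low_failure
          - iv_high_success
          - iv_high_failure
      - name: conditions
        label: Conditions associated with additional iron need
        levels: [absent, present]
      - name: activity
        label: IBD activity status
        levels: [inactive, active]
    treatments:
      - name: none
        label: None
      - name: ibd_medication
        label: Adjusting IBD medication only
      - name: oral_iron
        label: Oral iron
      - name: iv_low
        label: Low-dose IV iron
      - name: iv_high
        label: High-dose IV iron
  IDA:
    variables:
      - name: prev_treatment
        label: Previous treatment of iron deficiency
        levels:
          - none
          - oral_success
          - oral_failure
          - iv_low_success
          - iv_low_failure
          - iv_high_success
          - iv_high_failure
      - name: hb_band
        label: Haemoglobin level (g/dL)
        levels: [hb_lt8, hb_8_10, hb_10_12]
      - name: symptoms
        label: Physical symptoms of iron depletion
        levels: [absent, present]
      - name: conditions
        label: Conditions associated with additional iron need
        levels: [absent, present]
      - name: activity
        label: IBD activity status
        levels: [inactive, active]
    treatments:
      - name: none
        label: None
      - name: oral_iron
        label: Oral iron
      - name: iv_low
        label: Low-dose IV iron
      - name: iv_high
        label: High-dose IV iron
      - name: iv_esa
        label: IV iron + ESA
      - name: transfusion
        label: Blood transfusion
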