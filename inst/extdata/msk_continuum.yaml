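spec_version: '1'
name: msk_infection_continuum
index_element: diabetes_mellitus
anchor_elements:
- osteomyelitis
- septic_arthritis
- infectious_myositis
phases:
- label: primary risk factors
  elements:
  - element_id: diabetes_mellitus
    code_criteria:
    - code_system: ICD9
      prefixes:
      - '249'
      - '250'
      require_amputation: no
    - code_system: ICD10
      prefixes:
      - E08
      - E09
      - E10
      - E11
      - E13
      require_amputation: no
    lab_criteria:
    - analyte: hba1c
      aggregation: max
      comparator: ge
      threshold: 6.5
      units: '%'
    med_criteria:
    - drug_classes:
      - insulin
      - metformin
      - sulfonylurea
      - thiazolidinedione
      - dpp4_inhibitor
      - glp1_agonist
      - sglt2_inhibitor
      exclude_routes: topical
  - element_id: peripheral_vascular_disease
    code_criteria:
    - code_system: ICD9
      prefixes:
      - '4439'
      - '440'
      require_amputation: no
    - code_system: ICD10
      prefixes:
      - I70
      - I739
      require_amputation: no
- label: secondary risk factors
  elements:
  - element_id: osteomyelitis
    code_criteria:
    - code_system: ICD9
      prefixes: '730'
      require_amputation: no
    - code_system: ICD10
      prefixes: M86
      require_amputation: no
  - element_id: multiple_infections
    composite:
      member_elements:
      - osteomyelitis
      - septic_arthritis
      - infectious_myositis
      min_count: 2
- label: infection-related outcomes
  elements:
  - element_id: sepsis
    code_criteria:
    - code_system: ICD9
      prefixes:
      - 038
      - '99591'
      - '99592'
      require_amputation: no
    - code_system: ICD10
      prefixes:
      - A40
      - A41
      - R652
      require_amputation: no
  - element_id: antibiotics
    med_criteria:
    - drug_classes:
      - penicillin
      - cephalosporin
      - fluoroquinolone
      - glycopeptide
      - macrolide
      - tetracycline
      - carbapenem
      - aminoglycoside
      - lincosamide
      - oxazolidinone
      - sulfonamide_antibiotic
      exclude_routes: topical
- label: surgical interventions
  elements:
  - element_id: surgical_procedure
    code_criteria:
    - code_system: procedure
      require_amputation: no
    window:
      anchor: index_infection_date
      start_offset_days: 0
      end_offset_days: 90
  - element_id: amputation
    code_criteria:
    - code_system: procedure
      require_amputation: yes
    window:
      anchor: index_infection_date
      start_offset_days: 0
      end_offset_days: 90
helper_elements:
- element_id: septic_arthritis
  code_criteria:
  - code_system: ICD9
    prefixes: '711'
    require_amputation: no
  - code_system: ICD10
    prefixes: M00
    require_amputation: no
- element_id: infectious_myositis
  code_criteria:
  - code_system: ICD9
    prefixes: '72886'
    require_amputation: no
  - code_system: ICD10
    prefixes: M600
    require_amputation: no
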