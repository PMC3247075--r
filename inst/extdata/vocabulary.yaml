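# Controlled vocabularies and collapse maps for census classification.
#
# specialty: the 11 medical-specialty categories (NICE-derived taxonomy).
# intervention: 15 "active" categories (UKCRC-derived) plus the two
#   control categories. "Pharmacological" is the one pharmacological
#   active category; every other active category is non-pharmacological.
# outcome: the 23 outcome categories, listed IN PRIORITY ORDER -- an
#   outcome eligible for several categories is assigned the one highest
#   on this list. The order here is a documented default (mortality and
#   morbidity categories first, broad sign/symptom categories last); it
#   is configuration, not a reproduction of any published order, and
#   should be supplied explicitly for reproduction work.
# outcome_group11: collapse of the 23 outcome categories onto the 11
#   groups used for stratified summaries. Membership of the two residual
#   groups ("semi-objective" / "subjective") is an assumption chosen for
#   arithmetic consistency with published group sizes; edit to taste.

specialty:
  - Cancer
  - Cardiovascular
  - Central nervous system/musculoskeletal
  - Digestive/endocrine, nutritional and metabolic
  - Gynaecology, pregnancy and birth
  - Infectious diseases
  - Mental health and behavioural conditions
  - Pathological conditions, symptoms and signs
  - Respiratory diseases
  - Urogenital
  - Other

intervention_active:
  - Pharmacological
  - Vaccines
  - Surgical
  - Medical devices
  - Cellular and gene
  - Radiotherapy
  - Physical
  - Educational
  - Behavioural
  - Screening
  - Complementary
  - Psychological
  - Resources and infrastructure
  - Complex
  - Other

intervention_control:
  - Control
  - Placebo

outcome_priority_order:
  - All-cause mortality
  - Cause-specific mortality
  - Major morbidity event
  - Composite (mortality/morbidity only)
  - Composite (at least 1 non-mortality/morbidity)
  - Obstetric outcomes
  - Surgical/device related success/failure
  - Infection/onset of new acute/chronic disease
  - Adverse events
  - Withdrawals/dropouts
  - Internal structure
  - External structure
  - Biological markers
  - General physical health
  - Consumption
  - Resource use
  - Hospital stay/process measures
  - Quality of life/functioning
  - Mental health outcomes
  - Pain
  - Satisfaction with care
  - Signs/symptoms reflecting continuation/end of condition
  - Other

outcome_group11:
  All-cause mortality: All-cause mortality
  Cause-specific mortality: Cause-specific mortality/major morbidity event/composite (mortality or morbidity)
  Major morbidity event: Cause-specific mortality/major morbidity event/composite (mortality or morbidity)
  Composite (mortality/morbidity only): Cause-specific mortality/major morbidity event/composite (mortality or morbidity)
  Signs/symptoms reflecting continuation/end of condition: Signs/symptoms reflecting continuation/end of condition
  Adverse events: Adverse events
  Infection/onset of new acute/chronic disease: Infection/onset of new acute/chronic disease
  Biological markers: Biological markers
  General physical health: General physical health
  Obstetric outcomes: Obstetric outcomes
  Resource use: Resource use/hospital stay/process
  Hospital stay/process measures: Resource use/hospital stay/process
  Withdrawals/dropouts: Other outcomes (semi-objective)
  Internal structure: Other outcomes (semi-objective)
  External structure: Other outcomes (semi-objective)
  Consumption: Other outcomes (semi-objective)
  Composite (at least 1 non-mortality/morbidity): Other outcomes (semi-objective)
  Satisfaction with care: Other outcomes (semi-objective)
  Quality of life/functioning: Other outcomes (subjective)
  Pain: Other outcomes (subjective)
  Mental health outcomes: Other outcomes (subjective)
  Surgical/device related success/failure: Other outcomes (subjective)
  Other: Other outcomes (subjective)
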