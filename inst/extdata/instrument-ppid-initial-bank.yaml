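schema: hrqol-bank-stub/1
name: ppid-initial-bank
description: >-
  Metadata stub for the 42-item bank assembled from interviews with
  veterinarians and owners, a literature review and clinical record
  review.  Five items were removed before the survey because they
  duplicated other items; their individual wordings were not recorded,
  so only counts are kept here.  The fielded bank is ppid-survey-37.
n_items_identified: 42
n_removed_pre_survey: 5
survey_bank: ppid-survey-37
domains:
  - demeanour
  - appearance
  - condition
  - health
  - appetite
  - ingestion
  - management
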