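dx_categories:
  CHEMOTHERAPY: 45
  INFECTION:
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
  - 76
  - 77
  - 122
  - 123
  - 126
  - 135
  - 159
  - 197
  - 246
  - 249
  MALIGNANCY:
  - 11
  - 12
  - 13
  - 14
  - 15
  - 16
  - 17
  - 18
  - 19
  - 20
  - 21
  - 22
  - 23
  - 24
  - 25
  - 26
  - 27
  - 28
  - 29
  - 30
  - 31
  - 32
  - 33
  - 34
  - 35
  - 36
  - 37
  - 38
  - 39
  - 40
  - 41
  - 42
  - 43
  TOX_CYTOPENIA:
  - 59
  - 60
  - 62
  - 63
  - 64
  TOX_OTHER:
  - 55
  - 83
  - 95
  - 107
  - 131
  - 152
  - 153
  - 157
  - 237
  - 238
  - 250
  - 251
  - 252
  - 253
proc_categories:
  CANCER_PROCEDURE:
  - 1
  - 2
  - 3
  - 9
  - 61
  - 64
  - 66
  - 67
  - 89
  - 99
  - 170
  CHEMOTHERAPY: 224
dx_overrides:
- ccs_group: 237
  icd9: '99931'
  category: INFECTION
- ccs_group: 237
  icd9: '99662'
  category: INFECTION
- ccs_group: 237
  icd9: '99667'
  category: INFECTION
- ccs_group: 237
  icd9: '99669'
  category: INFECTION
hct_proc_group: 64
icu_dx_groups:
- 131
- 107
- 249
cytopenia_groups:
- 59
- 60
- 62
- 63
- 64
excluded_cancer_groups: 44
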