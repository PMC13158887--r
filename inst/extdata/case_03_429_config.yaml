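# Run configuration for the bundled dial-painter case study.
# Worker metadata: began dial painting in August 1923 at age 15, worked four
# years, lip-pointing assumed discontinued after 1926 (default cutoff
# 1927-01-01), died 1976. Birth date is set so that she is exactly 15 at the
# start of work; death date is set mid-year (only the year is recorded).
worker:
  birth_date: 1908-08-01
  work_start: 1923-08-01
  work_end: 1927-08-01
  lip_pointing_cutoff: 1927-01-01
  death_date: 1976-07-01
post_ratio: 0.01
files:
  # empty values mean the package's bundled defaults
  chain: ""
  biokinetics: ""
  dosimetry: ""
  measurements: ""
mode:
  estimation: all_measurements   # or single_measurement
  selector: latest               # used in single_measurement mode
seed: 1
# External radiotherapy received by the case (1973), carried as report
# metadata only; never added to internal doses.
metadata:
  radiotherapy_note: >-
    Pre-operative 30 Gy plus post-operative electron-beam courses (72 Gy
    mastoid tumour dose) recorded in 1973; external therapy doses are not
    part of the internal dose reconstruction.
legacy:
  anl_systemic_intake_uCi: 273.7
  anl_bone_dose_Gy: 47.22
  anl_target_note: >-
    ANL's 47.22 Gy refers to bone volume; the present endosteal estimate uses
    a different target, so numerical comparison is cautioned against.
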