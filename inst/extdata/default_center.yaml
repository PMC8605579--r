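# Default case-study center configuration: four aggregate examination sets
# over five resources. Prices and original limits are synthetic placeholders
# (the real per-set prices were never published; the range is 20,000-100,000
# NTD).
sets:
- name: set1_basic_colono
  price: 25000
  original_limit: 2
- name: set2_basic_breast_colono
  price: 28000
  original_limit: 22
- name: set3_exquisite_mri
  price: 60000
  original_limit: 3
- name: set4_elite_mri_dwi
  price: 85000
  original_limit: 3
resources:
- name: basic
  ideal_level: 36
  overage_fraction: 0.5
- name: breast
  ideal_level: 36
  overage_fraction: 0.5
- name: gastroenteroscope
  ideal_level: 24
  overage_fraction: 0.5
- name: mri
  ideal_level: 4
  overage_fraction: 0.5
- name: dwi
  ideal_level: 2
  overage_fraction: 0.5
requirements:
  set1_basic_colono: [basic, gastroenteroscope]
  set2_basic_breast_colono: [basic, breast, gastroenteroscope]
  set3_exquisite_mri: [basic, mri]
  set4_elite_mri_dwi: [basic, mri, dwi]
cost_schedule:
  marginal: [2500, 2500, 2500, 5000, 5000, 5000, 10000, 10000, 10000, 20000]
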