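# Combined scenario: fresher units (age <= 7 d) for any ICU patient,
# age <= 14 d for cardiac-surgery patients outside the ICU.
name: icu-cs
groups:
  ICU: 7
  CS: 14
baseline_method: LO
shelf_life: 42
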