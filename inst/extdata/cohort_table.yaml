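# Demographic / clinical summary inputs for a three-group female cohort
# (BPD patients, non-patient comparisons, cluster-C patients), as printed
# in a typical descriptive table: per-group (n, mean, sd) summaries and
# 2x2 crosstab counts of diagnoses and medication (patient groups only).
one_sample_t:
  rating_change_NPC: {mean: 16.67, sd: 41.81, "n": 38}
  rating_change_BPD: {mean: 11.90, sd: 31.41, "n": 47}
  rating_change_CPD: {mean: 11.74, sd: 28.46, "n": 21}
anova:
  age:
    "n": [48, 39, 21]
    mean: [30.79, 28.67, 31.48]
    sd: [9.21, 10.70, 11.80]
  iq:
    "n": [48, 38, 21]
    mean: [96.88, 100.73, 98.45]
    sd: [10.08, 11.38, 9.26]
chisq:
  major_depressive_disorder: {a: 42, b: 6, c: 13, d: 8}
  substance_abuse: {a: 21, b: 27, c: 1, d: 20}
  avoidant_pd: {a: 21, b: 27, c: 15, d: 6}
  paranoid_pd: {a: 14, b: 34, c: 0, d: 21}
  antidepressants: {a: 31, b: 17, c: 8, d: 13}
  ptsd: {a: 17, b: 31, c: 3, d: 18}
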