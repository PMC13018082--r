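# LR bands for ACMG/AMP co-segregation evidence (PP1 pathogenic
# direction, BS4 benign direction), following the Tavtigian-style odds
# bands 2.08 / 4.33 / 18.7 / 350 and their reciprocals. Each entry is the
# lower LR bound of its interval; an LR equal to a bound belongs to the
# higher interval. Fully user-replaceable.
thresholds:
- label: BS4_strong
  lower: 0
- label: BS4_moderate
  lower: 0.053476
- label: BS4_supporting
  lower: 0.230947
- label: no_evidence
  lower: 0.480769
- label: PP1_supporting
  lower: 2.08
- label: PP1_moderate
  lower: 4.33
- label: PP1_strong
  lower: 18.7
- label: PP1_very_strong
  lower: 350
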