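population: legacy-NL
provenance: SYNTHETIC illustrative parameter set assembled from widely cited literature
  risk figures (not a registry fit); replace with your own fitted parameters for clinical
  use.
curves:
- gene: BRCA1
  cancer: BC
  sex: F
  carrier_status: population
  r: 0.1
  mu: 62.0
  sigma: 14.0
- gene: BRCA1
  cancer: OC
  sex: F
  carrier_status: population
  r: 0.012
  mu: 65.0
  sigma: 13.0
- gene: BRCA2
  cancer: BC
  sex: F
  carrier_status: population
  r: 0.1
  mu: 62.0
  sigma: 14.0
- gene: BRCA2
  cancer: OC
  sex: F
  carrier_status: population
  r: 0.012
  mu: 65.0
  sigma: 13.0
- gene: BRCA1
  cancer: BC
  sex: F
  carrier_status: carrier
  r: 0.8
  mu: 50.0
  sigma: 14.0
- gene: BRCA1
  cancer: OC
  sex: F
  carrier_status: carrier
  r: 0.6
  mu: 55.0
  sigma: 12.0
- gene: BRCA2
  cancer: BC
  sex: F
  carrier_status: carrier
  r: 0.77
  mu: 55.0
  sigma: 14.0
- gene: BRCA2
  cancer: OC
  sex: F
  carrier_status: carrier
  r: 0.33
  mu: 60.0
  sigma: 11.0
cbc: []
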