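population: UK
provenance: SYNTHETIC illustrative parameter set assembled from widely cited literature
  risk figures (not a registry fit); replace with your own fitted parameters for clinical
  use.
curves:
- gene: BRCA1
  cancer: BC
  sex: F
  carrier_status: population
  r: 0.12
  mu: 62.0
  sigma: 14.0
- gene: BRCA1
  cancer: OC
  sex: F
  carrier_status: population
  r: 0.018
  mu: 65.0
  sigma: 13.0
- gene: BRCA2
  cancer: BC
  sex: F
  carrier_status: population
  r: 0.12
  mu: 62.0
  sigma: 14.0
- gene: BRCA2
  cancer: OC
  sex: F
  carrier_status: population
  r: 0.018
  mu: 65.0
  sigma: 13.0
- gene: BRCA2
  cancer: PANC
  sex: F
  carrier_status: population
  r: 0.015
  mu: 72.0
  sigma: 10.0
- gene: BRCA2
  cancer: PANC
  sex: M
  carrier_status: population
  r: 0.015
  mu: 72.0
  sigma: 10.0
- gene: PALB2
  cancer: BC
  sex: F
  carrier_status: population
  r: 0.12
  mu: 62.0
  sigma: 14.0
- gene: PALB2
  cancer: OC
  sex: F
  carrier_status: population
  r: 0.018
  mu: 65.0
  sigma: 13.0
- gene: PALB2
  cancer: PANC
  sex: F
  carrier_status: population
  r: 0.015
  mu: 72.0
  sigma: 10.0
- gene: PALB2
  cancer: PANC
  sex: M
  carrier_status: population
  r: 0.015
  mu: 72.0
  sigma: 10.0
- gene: BRCA1
  cancer: BC
  sex: F
  carrier_status: carrier
  r: 0.72
  mu: 52.0
  sigma: 16.0
- gene: BRCA1
  cancer: OC
  sex: F
  carrier_status: carrier
  r: 0.44
  mu: 57.0
  sigma: 12.0
- gene: BRCA2
  cancer: BC
  sex: F
  carrier_status: carrier
  r: 0.69
  mu: 58.0
  sigma: 16.0
- gene: BRCA2
  cancer: OC
  sex: F
  carrier_status: carrier
  r: 0.17
  mu: 62.0
  sigma: 11.0
- gene: BRCA2
  cancer: PANC
  sex: F
  carrier_status: carrier
  r: 0.03
  mu: 70.0
  sigma: 10.0
- gene: BRCA2
  cancer: PANC
  sex: M
  carrier_status: carrier
  r: 0.03
  mu: 70.0
  sigma: 10.0
- gene: PALB2
  cancer: BC
  sex: F
  carrier_status: carrier
  r: 0.53
  mu: 58.0
  sigma: 16.0
- gene: PALB2
  cancer: OC
  sex: F
  carrier_status: carrier
  r: 0.05
  mu: 63.0
  sigma: 11.0
- gene: PALB2
  cancer: PANC
  sex: F
  carrier_status: carrier
  r: 0.025
  mu: 70.0
  sigma: 10.0
- gene: PALB2
  cancer: PANC
  sex: M
  carrier_status: carrier
  r: 0.025
  mu: 70.0
  sigma: 10.0
cbc:
- gene: BRCA1
  carrier_status: carrier
  rate: 0.02
- gene: BRCA1
  carrier_status: population
  rate: 0.004
- gene: BRCA2
  carrier_status: carrier
  rate: 0.015
- gene: BRCA2
  carrier_status: population
  rate: 0.004
- gene: PALB2
  carrier_status: carrier
  rate: 0.01
- gene: PALB2
  carrier_status: population
  rate: 0.004
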