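provenance:
  anchors: paper
  washout: paper
  pKa: fixture (phosphate 6.8 paper-fixed)
pKa:
  co2pair: 3.646498580796
  phosphate: 6.8
  ammonia: 9.15
  formate: 3.75
anchors:
  cortex:
    Na: 140.0
    K: 4.0
    Cl: 100.0
    HCO3: 25.0
    H2CO3: 0.00441
    CO2: 1.45
    phos_total: 1.45
    urea: 5.0
    amm_total: 1.0
    form_total: 1.0
    glucose: 5.0
    protein: 2.0
    pH: 7.4
  omim:
    Na: 299.0
    K: 8.0
    Cl: 280.4
    HCO3: 25.0
    H2CO3: 0.00441
    CO2: 1.45
    phos_total: 1.45
    urea: 60.0
    amm_total: 3.9
    form_total: 1.0
    glucose: 6.25
    protein: 2.0
    pH: 7.4
  tip:
    Na: 239.0
    K: 15.0
    Cl: 236.5
    HCO3: 25.0
    H2CO3: 0.00441
    CO2: 1.45
    phos_total: 1.45
    urea: 200.0
    amm_total: 8.95
    form_total: 1.0
    glucose: 7.5
    protein: 2.0
    pH: 7.3
nkcc2_washout:
  omim:
    Na: 204.0
    K: 5.6
    Cl: 193.0
    urea: 28.0
  tip:
    Na: 160.0
    K: 7.0
    Cl: 149.0
    urea: 56.0
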