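# Example coefficient file for the empirical Vcmax25 models that require
# externally supplied, PFT-specific parameters (EM1, EM2, EM5). The values
# below are SYNTHETIC PLACEHOLDERS chosen only to exercise the code paths:
# they are NOT the canonical parameters, which live in the source
# publications of each model. Replace every block before any scientific use.
#
# EM1/EM2 (linear in LNC):  Vcmax25 = n1 * LNC + n2
# EM5 (linear in climate):  Vcmax25 = b_pp*PP + b_tair*Tair + b_par*PAR
#                                     + b_co2*CO2 + b0
EM1:
  - {pft: CRO, n1: 30.0, n2: 5.0}
  - {pft: DBF, n1: 25.0, n2: 8.0}
  - {pft: EBF, n1: 20.0, n2: 10.0}
  - {pft: ENF, n1: 22.0, n2: 9.0}
  - {pft: MF,  n1: 24.0, n2: 8.0}
  - {pft: GRA, n1: 28.0, n2: 6.0}
  - {pft: SH,  n1: 26.0, n2: 7.0}
  - {pft: WET, n1: 27.0, n2: 6.0}
EM2:
  - {pft: CRO, n1: 30.0, n2: 5.0}
  - {pft: DBF, n1: 25.0, n2: 8.0}
  - {pft: EBF, n1: 14.0, n2: 10.0}   # smaller n1 for EBF: implicit P limitation
  - {pft: ENF, n1: 22.0, n2: 9.0}
  - {pft: MF,  n1: 24.0, n2: 8.0}
  - {pft: GRA, n1: 28.0, n2: 6.0}
  - {pft: SH,  n1: 26.0, n2: 7.0}
  - {pft: WET, n1: 27.0, n2: 6.0}
EM5:
  - {pft: CRO, b_pp: 0.004, b_tair: 0.5, b_par: 0.02, b_co2: 0.01, b0: 30.0}
  - {pft: DBF, b_pp: 0.003, b_tair: 0.6, b_par: 0.02, b_co2: 0.01, b0: 28.0}
  - {pft: EBF, b_pp: 0.002, b_tair: 0.4, b_par: 0.015, b_co2: 0.01, b0: 26.0}
  - {pft: ENF, b_pp: 0.003, b_tair: 0.5, b_par: 0.02, b_co2: 0.01, b0: 27.0}
  - {pft: MF,  b_pp: 0.003, b_tair: 0.5, b_par: 0.02, b_co2: 0.01, b0: 28.0}
  - {pft: GRA, b_pp: 0.004, b_tair: 0.4, b_par: 0.025, b_co2: 0.01, b0: 32.0}
  - {pft: SH,  b_pp: 0.004, b_tair: 0.4, b_par: 0.02, b_co2: 0.01, b0: 30.0}
  - {pft: WET, b_pp: 0.003, b_tair: 0.4, b_par: 0.02, b_co2: 0.01, b0: 30.0}
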