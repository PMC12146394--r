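# Calibrated crop parameter sets for two hot-pepper accessions under
# greenhouse control (28/18 C day/night) and heat-stress (30/22 C) regimes.
# Column meanings:
#   WA    potential growth rate, kg ha-1 per MJ m-2 intercepted PAR
#   HI    harvest index (yield / above-ground biomass)
#   TB    optimal temperature for growth, C
#   TG    base (minimum) temperature for growth, C
#   DMLA  maximum leaf area index
#   DLAP1/DLAP2  packed point codes of the leaf-area development S-curve
#                (integer part: percent of season; fraction: fraction of DMLA)
#   PPL1/PPL2    packed point codes of the plant-population curve
#                (integer part: plants m-2; fraction: fraction of DMLA)
#   CNY   normal N fraction of yield
#   BN1/BN2/BN3  normal N fraction of biomass at emergence/midseason/maturity
#   PHU   potential heat units, planting to physiological maturity, C day
defaults:
  DLAI: 0.99          # greenhouse harvests fall within active growth
  DLAI_field: 0.9     # open-field crops harvested as leaf area declines
  k_ext: 0.65         # Beer's-law canopy light-extinction coefficient
  hui_flower: 0.30    # heat-unit index at which harvest index starts accruing
  WA_field_scale: 0.81818182  # 27/33: field-to-greenhouse RUE ratio
PHR18:
  control: {WA: 33, HI: 0.57, TB: 30, TG: 10, DMLA: 3.8, DLAP1: 10.19, DLAP2: 50.95,
            PPL1: 1.08, PPL2: 4.99, CNY: 0.03, BN1: 0.03, BN2: 0.007, BN3: 0.003, PHU: 1800}
  heat:    {WA: 24, HI: 0.58, TB: 30, TG: 10, DMLA: 3.8, DLAP1: 10.19, DLAP2: 45.95,
            PPL1: 2.08, PPL2: 6.99, CNY: 0.03, BN1: 0.03, BN2: 0.003, BN3: 0.001, PHU: 3000}
PHR23:
  control: {WA: 37, HI: 0.65, TB: 30, TG: 10, DMLA: 6.1, DLAP1: 10.19, DLAP2: 65.95,
            PPL1: 1.08, PPL2: 4.99, CNY: 0.03, BN1: 0.03, BN2: 0.006, BN3: 0.003, PHU: 1800}
  heat:    {WA: 25, HI: 0.42, TB: 30, TG: 10, DMLA: 6.1, DLAP1: 10.19, DLAP2: 40.95,
            PPL1: 2.08, PPL2: 8.99, CNY: 0.03, BN1: 0.03, BN2: 0.003, BN3: 0.001, PHU: 3000}
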