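# Per-site generating defaults for the two packaged acid-sulfate-chloride
# springs (Norris Geyser Basin). Rates and ratios are the fitted/observed
# values for each site; profile parameters k1 and l_f are derived at load
# time from (o2_flux, thiele, o2_bulk, d_e) -- see siteConfig().
osp:
  fe_k: 0.05               # day-1, Fe(III)-oxide accretion rate constant
  fe_x0: 0.5               # umol cm-2, initial oxide loading
  dna_r: 0.028             # day-1, DNA accumulation rate constant
  dna_x0: 10.0             # ng cm-2
  coloniz_rate_rod: 3700000.0     # cells cm-2 day-1 (rod-shaped bacteria)
  coloniz_rate_coccus: 920000.0   # cells cm-2 day-1 (coccoid archaea)
  o2_bulk: 55.0            # uM, interface/bulk O2 (2013 profile campaign)
  o2_flux: 0.000114        # umol cm-2 s-1, net areal O2 flux (2013)
  thiele: 28.0             # dimensionless, fitted Thiele modulus (2013)
  d_e: 0.000045            # cm2 s-1, effective O2 diffusivity at 70-75 C
  as_fe_ratio: 0.5
  p_fe_ratio: 0.01
  w_fe_ratio: 0.002
  velocity: 3.5            # cm s-1, channel velocity (range 2-5)
  community:
    start_day: 4.0
    rod_taxon: Hydrogenobaculum
    rod_start: 0.85
    rod_decline_per_day: 0.01
    rod_floor: 0.01
    feox_taxon: M_yellowstonensis
    feox_fraction: 0.15
    heterotrophs:
      - taxon: Geoarchaeota
        midpoint: 40.0
        width: 8.0
      - taxon: NAG2
        midpoint: 45.0
        width: 8.0
      - taxon: Other_Sulfolobales
        midpoint: 50.0
        width: 10.0
      - taxon: Thaumarchaeota
        midpoint: 55.0
        width: 10.0
beowulf:
  fe_k: 0.047
  fe_x0: 0.3
  dna_r: 0.043
  dna_x0: 5.0
  coloniz_rate_rod: 6800000.0
  coloniz_rate_coccus: 860000.0
  o2_bulk: 44.0
  o2_flux: 0.000164        # 2011 campaign
  thiele: 60.0
  d_e: 0.000045
  as_fe_ratio: 0.67
  p_fe_ratio: 0.01
  w_fe_ratio: 0.002
  velocity: 25.0           # cm s-1 (range 20-30)
  community:
    start_day: 4.0
    rod_taxon: Hydrogenobaculum
    rod_start: 0.85
    rod_decline_per_day: 0.01
    rod_floor: 0.01
    feox_taxon: M_yellowstonensis
    feox_fraction: 0.15
    heterotrophs:
      - taxon: Sulfolobales_gp3
        midpoint: 35.0
        width: 8.0
      - taxon: NAG2
        midpoint: 45.0
        width: 8.0
      - taxon: NAG3
        midpoint: 50.0
        width: 10.0
      - taxon: Thaumarchaeota
        midpoint: 55.0
        width: 10.0
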