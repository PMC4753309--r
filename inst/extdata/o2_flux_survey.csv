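# Net areal O2 fluxes, penetration depths and Thiele moduli measured by
# microelectrode in thermoacidic Fe(III)-oxide mats (Norris Geyser Basin).
# penetration_depth_um: midpoint used where a range was reported; thiele NA
# where not determined.
spring,temperature_c,sample_date,flux_umol_cm2_s,penetration_depth_um,thiele
One Hundred Spring Plain,75,2013-05-21,1.14e-4,950,28
One Hundred Spring Plain,75,2010-08-18,1.41e-4,750,30
Beowulf,68,2011-07-06,1.64e-4,625,60
Beowulf,60,2004-07-13,5e-5,500,NA
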