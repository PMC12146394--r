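# Per-plant fresh-mass yield summary of the two-year greenhouse heat-stress
# trial: means +/- dispersion and tabulated harvest index, by accession,
# condition and harvest day after treatment start.
day,accession,condition,total_fresh_g,total_fresh_sd,fruit_fresh_g,fruit_fresh_sd,harvest_index
35,PHR18,control,326,108,91,51,0.28
35,PHR18,heat,178,123,60,36,0.34
35,PHR23,control,803,180,312,105,0.39
35,PHR23,heat,950,507,513,286,0.54
75,PHR18,control,1508,314,825,150,0.55
75,PHR18,heat,980,290,565,228,0.58
75,PHR23,control,2002,401,1303,277,0.65
75,PHR23,heat,1560,208,846,152,0.54
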