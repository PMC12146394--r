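# Morphological and nitrogen summary of the greenhouse trial (means +/-
# dispersion): fruit counts, tissue moisture, leaf area index, height, stem
# thickness and total plant N by condition, accession and harvest day.
day,condition,accession,n_fruits,n_fruits_sd,moisture_pct,moisture_sd,lai,lai_sd,height_cm,height_sd,stem_mm,stem_sd,total_n_g,total_n_sd
35,control,PHR18,38,18,87,2,1.51,0.48,72,9,13.62,1.42,0.18,0.05
35,control,PHR23,54,12,85,1,4.01,0.62,86,13,16.12,2.27,0.44,0.13
35,heat,PHR18,28,15,77,22,0.72,0.61,59,18,10.74,2.84,0.10,0.05
35,heat,PHR23,52,18,87,2,3.22,2.14,81,27,15.35,4.30,0.49,0.30
75,control,PHR18,119,54,88,4,2.71,0.37,123,12,16.28,1.94,0.54,0.11
75,control,PHR23,65,23,86,1,4.12,0.95,128,13,19.23,3.17,0.80,0.23
75,heat,PHR18,94,52,86,2,2.10,0.64,102,27,13.41,2.47,0.43,0.17
75,heat,PHR23,47,3,87,3,2.71,0.78,105,33,19.91,6.02,0.58,0.14
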