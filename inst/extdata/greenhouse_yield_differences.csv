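# Tabulated integer percent yield differences (heat vs control) from the
# greenhouse trial, per accession and harvest day.
day,accession,pct_total,pct_fruit
35,PHR18,-45,-34
35,PHR23,18,64
75,PHR18,-35,-32
75,PHR23,-22,-35
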