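# Published multi-site warming-scenario results: simulated dry yields
# (Mg ha-1) for reference weather (2014-2023) and +3/+4/+5 C perturbations,
# with the tabulated integer percent change in parentheses columns.
accession,province,city,reference,yield_p3,pct_p3,yield_p4,pct_p4,yield_p5,pct_p5
PHR18,GW,Hoengseong,7.53,4.88,-35,4.85,-36,4.82,-36
PHR18,GG,Anseong,8.13,5.57,-31,5.58,-31,5.54,-32
PHR18,CB,Jecheon,9.04,5.99,-34,6.15,-32,6.04,-33
PHR18,CN,Dangjin,10.61,6.12,-42,5.95,-44,5.94,-44
PHR18,CN,Cheongyang,9.58,5.56,-42,5.45,-43,5.37,-44
PHR18,GB,Yeongyang,9.21,6.20,-33,6.21,-33,6.21,-33
PHR18,GN,Hamyang,11.16,7.24,-35,7.18,-36,7.14,-36
PHR18,JN,Sinan,11.17,6.69,-40,6.63,-41,6.56,-41
PHR18,JN,Haenam,10.92,6.20,-43,6.41,-41,5.99,-45
PHR23,GW,Hoengseong,9.36,4.97,-47,4.93,-47,4.88,-48
PHR23,GG,Anseong,10.12,5.65,-44,5.65,-44,5.61,-45
PHR23,CB,Jecheon,11.15,6.15,-45,6.20,-44,6.15,-45
PHR23,CN,Dangjin,13.17,6.24,-53,6.10,-54,6.09,-54
PHR23,CN,Cheongyang,11.90,5.83,-51,5.71,-52,5.62,-53
PHR23,GB,Yeongyang,11.48,6.31,-45,6.31,-45,6.29,-45
PHR23,GN,Hamyang,13.84,7.37,-47,7.31,-47,7.27,-48
PHR23,JN,Sinan,13.90,6.94,-50,6.87,-51,6.80,-51
PHR23,JN,Haenam,13.39,6.33,-53,6.50,-51,6.41,-52
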