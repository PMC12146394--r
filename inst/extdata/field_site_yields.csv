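# Measured vs simulated dry pepper yields (Mg ha-1) at the open-field
# calibration site (Cheonan, phu_test = 0) and the nine potential-heat-unit
# test locations across seven Korean provinces (phu_test = 1), with the
# tabulated measured/simulated ratio.
site,province,city,year,measured,measured_sd,simulated,ratio,phu_test
cheonan,CN,Cheonan,2024,8.13,1.77,8.05,1.01,0
hoengseong,GW,Hoengseong,2021,8.23,0.54,7.81,1.05,1
anseong,GG,Anseong,2021,9.01,1.48,8.18,1.10,1
anseong,GG,Anseong,2023,8.89,1.73,7.30,1.22,1
jecheon,CB,Jecheon,2021,8.57,2.78,9.42,0.91,1
jecheon,CB,Jecheon,2022,7.87,0.19,8.49,0.93,1
jecheon,CB,Jecheon,2023,8.93,0.00,9.46,0.94,1
dangjin,CN,Dangjin,2021,7.16,2.27,7.79,0.92,1
cheongyang,CN,Cheongyang,2021,6.17,0.09,7.26,0.85,1
cheongyang,CN,Cheongyang,2022,7.68,0.82,8.66,0.89,1
yeongyang,GB,Yeongyang,2021,7.83,1.47,7.70,1.02,1
yeongyang,GB,Yeongyang,2022,7.07,1.11,7.30,0.97,1
yeongyang,GB,Yeongyang,2023,8.39,0.31,9.49,0.88,1
hamyang,GN,Hamyang,2021,11.71,2.02,11.18,1.05,1
hamyang,GN,Hamyang,2023,11.28,1.69,11.16,1.01,1
sinan,JN,Sinan,2021,10.85,1.18,10.59,1.02,1
haenam,JN,Haenam,2021,7.46,2.61,7.43,1.00,1
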