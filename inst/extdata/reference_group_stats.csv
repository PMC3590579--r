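variable,group1_mean,group1_sd,group2_mean,group2_sd,group3_mean,group3_sd,group4_mean,group4_sd
n,30,0,40,0,40,0,30,0
age_years,24.87,2.69,56.59,8.75,64.98,9.26,60.03,8.24
hba1c_pct,5.49,0.25,5.67,0.31,6.79,0.60,9.85,1.81
fasting_glucose_mg_dl,92.69,3.19,97.70,15.76,128.06,28.77,166.96,59.07
hdl_mg_dl,44.81,5.60,52.94,20.64,42.78,16.26,43.39,14.65
mei_ss,3.43,1.23,2.92,0.89,2.78,1.27,2.37,0.88
mei_ls,4.22,1.41,3.53,0.99,3.02,1.48,2.34,0.96
di_percent,201.57,43.42,164.88,32.33,162.08,35.34,132.72,36.57
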