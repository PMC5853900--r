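variable,comparison,k,n,printed_p,printed_significant
climate_PC1,C3C4_vs_C3_all,14,19,0.019,FALSE
climate_PC1,C3C4_vs_C3_withC4,12,14,0.0018,TRUE
climate_PC1,C4_vs_C3C4,8,15,0.61,FALSE
soil_PC1,C3C4_vs_C3_all,10,19,0.65,FALSE
soil_PC1,C3C4_vs_C3_withC4,8,14,0.42,FALSE
soil_PC1,C4_vs_C3C4,6,15,0.61,FALSE
growth_season_temp,C3C4_vs_C3_all,14,19,0.019,FALSE
growth_season_temp,C3C4_vs_C3_withC4,13,14,0.00012,TRUE
growth_season_temp,C4_vs_C3C4,5,15,0.30,FALSE
min_temp,C3C4_vs_C3_all,13,19,0.064,FALSE
min_temp,C3C4_vs_C3_withC4,12,14,0.0018,TRUE
min_temp,C4_vs_C3C4,8,15,0.61,FALSE
min_precip,C3C4_vs_C3_all,7,19,0.36,FALSE
min_precip,C3C4_vs_C3_withC4,3,14,0.057,FALSE
min_precip,C4_vs_C3C4,7,15,1,FALSE
rainfall_seasonality,C3C4_vs_C3_all,14,19,0.019,FALSE
rainfall_seasonality,C3C4_vs_C3_withC4,12,14,0.0018,TRUE
rainfall_seasonality,C4_vs_C3C4,6,15,0.61,FALSE
OC,C3C4_vs_C3_all,11,19,0.36,FALSE
OC,C3C4_vs_C3_withC4,6,14,0.79,FALSE
OC,C4_vs_C3C4,5,15,0.30,FALSE
TEB,C3C4_vs_C3_all,8,19,0.65,FALSE
TEB,C3C4_vs_C3_withC4,5,14,0.42,FALSE
TEB,C4_vs_C3C4,6,15,0.61,FALSE
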