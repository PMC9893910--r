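scenario,lu_name,irrigated,yield_ton_ha,wf_m3_ton,nutrition_mcal_yr,caloric_cal_kg
base,alfalfa,TRUE,4.5,2699.7,91,230
base,apple,TRUE,11.2,1065.8,431,520
base,rf_barley,FALSE,0.9,3521.0,464,3540
base,barley,TRUE,2.1,2095.1,200,3540
base,rf_pea,FALSE,0.5,8497.6,61,420
base,rf_grape,FALSE,4.0,939.5,536,670
base,tobacco,TRUE,1.9,4149.6,0,0
base,tomato,TRUE,11.1,974.3,27,180
base,rf_wheat,FALSE,1.1,2926.1,4004,3640
base,wheat,TRUE,2.8,2206.7,1303,3640
BMP1,alfalfa,TRUE,3.93,2673.5,79,230
BMP1,apple,TRUE,9.28,1114.1,357,520
BMP1,rf_barley,FALSE,0.90,3499.3,464,3540
BMP1,barley,TRUE,2.10,2048.8,200,3540
BMP1,rf_pea,FALSE,0.50,8479.7,61,420
BMP1,rf_grape,FALSE,4.00,936.1,536,670
BMP1,tobacco,TRUE,1.67,4221.0,0,0
BMP1,tomato,TRUE,9.10,1028.1,22,180
BMP1,rf_wheat,FALSE,1.10,2909.0,4004,3640
BMP1,wheat,TRUE,2.74,2196.1,1275,3640
BMP2,alfalfa,TRUE,3.4,2529.3,68,230
BMP2,apple,TRUE,7.4,1144.9,284,520
BMP2,rf_barley,FALSE,0.9,3451.3,464,3540
BMP2,barley,TRUE,2.1,1953.1,200,3540
BMP2,rf_pea,FALSE,0.5,8477.3,61,420
BMP2,rf_grape,FALSE,4.0,927.7,536,670
BMP2,tobacco,TRUE,1.5,4075.8,0,0
BMP2,tomato,TRUE,3.7,2077.4,9,180
BMP2,rf_wheat,FALSE,1.1,2872.6,4004,3640
BMP2,wheat,TRUE,2.6,2173.0,1224,3640
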