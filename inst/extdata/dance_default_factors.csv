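table,age_group,anode,filter,glandularity_pct,thickness_mm,hvl_mm_al,value,role,source
g,,,,NA,20,0.3,0.39,grid,published_grid
g,,,,NA,20,0.5,0.541,grid,published_grid
g,,,,NA,20,0.8,0.683,grid,published_grid
g,,,,NA,30,0.3,0.273,grid,published_grid
g,,,,NA,30,0.5,0.405,grid,published_grid
g,,,,NA,30,0.8,0.555,grid,published_grid
g,,,,NA,40,0.3,0.207,grid,published_grid
g,,,,NA,40,0.5,0.319,grid,published_grid
g,,,,NA,40,0.8,0.46,grid,published_grid
g,,,,NA,50,0.3,0.165,grid,published_grid
g,,,,NA,50,0.5,0.259,grid,published_grid
g,,,,NA,50,0.8,0.388,grid,published_grid
g,,,,NA,60,0.3,0.136,grid,published_grid
g,,,,NA,60,0.5,0.215,grid,published_grid
g,,,,NA,60,0.8,0.333,grid,published_grid
g,,,,NA,70,0.3,0.115,grid,published_grid
g,,,,NA,70,0.5,0.182,grid,published_grid
g,,,,NA,70,0.8,0.289,grid,published_grid
g,,,,NA,80,0.3,0.099,grid,published_grid
g,,,,NA,80,0.5,0.157,grid,published_grid
g,,,,NA,80,0.8,0.254,grid,published_grid
g,,,,NA,90,0.3,0.0868,grid,published_grid
g,,,,NA,90,0.5,0.138,grid,published_grid
g,,,,NA,90,0.8,0.226,grid,published_grid
g,,,,NA,100,0.3,0.0774,grid,published_grid
g,,,,NA,100,0.5,0.123,grid,published_grid
g,,,,NA,100,0.8,0.204,grid,published_grid
g,,,,NA,110,0.3,0.0699,grid,published_grid
g,,,,NA,110,0.5,0.112,grid,published_grid
g,,,,NA,110,0.8,0.186,grid,published_grid
c,,,,100,20,0.3,0.863,grid,published_grid
c,,,,100,20,0.5,0.885,grid,published_grid
c,,,,100,20,0.8,0.917,grid,published_grid
c,,,,72,30,0.3,0.923,grid,published_grid
c,,,,72,30,0.5,0.935,grid,published_grid
c,,,,72,30,0.8,0.952,grid,published_grid
c,,,,50,40,0.3,0.998,grid,published_grid
c,,,,50,40,0.5,1,grid,published_grid
c,,,,50,40,0.8,1,grid,published_grid
c,,,,33,50,0.3,1.08,grid,published_grid
c,,,,33,50,0.5,1.07,grid,published_grid
c,,,,33,50,0.8,1.06,grid,published_grid
c,,,,21,60,0.3,1.15,grid,published_grid
c,,,,21,60,0.5,1.13,grid,published_grid
c,,,,21,60,0.8,1.11,grid,published_grid
c,,,,12,70,0.3,1.21,grid,published_grid
c,,,,12,70,0.5,1.19,grid,published_grid
c,,,,12,70,0.8,1.15,grid,published_grid
c,,,,7,80,0.3,1.26,grid,published_grid
c,,,,7,80,0.5,1.23,grid,published_grid
c,,,,7,80,0.8,1.18,grid,published_grid
c,,,,4,90,0.3,1.29,grid,published_grid
c,,,,4,90,0.5,1.26,grid,published_grid
c,,,,4,90,0.8,1.21,grid,published_grid
c,,,,3,100,0.3,1.31,grid,published_grid
c,,,,3,100,0.5,1.28,grid,published_grid
c,,,,3,100,0.8,1.22,grid,published_grid
c,,,,3,110,0.3,1.32,grid,published_grid
c,,,,3,110,0.5,1.29,grid,published_grid
c,,,,3,110,0.8,1.23,grid,published_grid
c,40-49,,,94.4,23.1785714285714,0.38,0.882,station,class_<26_dance
c,40-49,,,46.2,23.1785714285714,0.38,1.012,station,class_<26_volpara
c,50-64,,,91.1,23.1785714285714,0.38,0.89,station,class_<26_dance
c,50-64,,,47.4,23.1785714285714,0.38,1.009,station,class_<26_volpara
reference_sd,40-49,,,46.2,23.1785714285714,0.38,10.8,meta,class_<26
reference_sd,50-64,,,47.4,23.1785714285714,0.38,19.4,meta,class_<26
c,40-49,,,77.4,32.5454545454545,0.38,0.909,station,class_26-39_dance
c,40-49,,,37,32.5454545454545,0.38,1.047,station,class_26-39_volpara
c,50-64,,,66.4,32.5454545454545,0.38,0.944,station,class_26-39_dance
c,50-64,,,28.5,32.5454545454545,0.38,1.08,station,class_26-39_volpara
reference_sd,40-49,,,37,32.5454545454545,0.38,10.9,meta,class_26-39
reference_sd,50-64,,,28.5,32.5454545454545,0.38,12.5,meta,class_26-39
c,40-49,,,58.3,44.1764705882353,0.397,0.967,station,class_39-50_dance
c,40-49,,,30.2,44.1764705882353,0.397,1.083,station,class_39-50_volpara
c,50-64,,,42.9,44.1764705882353,0.397,1.028,station,class_39-50_dance
c,50-64,,,16.9,44.1764705882353,0.397,1.145,station,class_39-50_volpara
reference_sd,40-49,,,30.2,44.1764705882353,0.397,13.2,meta,class_39-50
reference_sd,50-64,,,16.9,44.1764705882353,0.397,9.7,meta,class_39-50
c,40-49,,,44.8,53.25,0.414,1.021,station,class_50-57_dance
c,40-49,,,23.1,53.25,0.414,1.121,station,class_50-57_volpara
c,50-64,,,29.1,53.25,0.414,1.092,station,class_50-57_dance
c,50-64,,,12.4,53.25,0.414,1.177,station,class_50-57_volpara
reference_sd,40-49,,,23.1,53.25,0.414,11.8,meta,class_50-57
reference_sd,50-64,,,12.4,53.25,0.414,6.3,meta,class_50-57
c,40-49,,,32.9,62.2222222222222,0.43,1.077,station,class_57-67_dance
c,40-49,,,17.9,62.2222222222222,0.43,1.153,station,class_57-67_volpara
c,50-64,,,19,62.2222222222222,0.43,1.147,station,class_57-67_dance
c,50-64,,,10.9,62.2222222222222,0.43,1.192,station,class_57-67_volpara
reference_sd,40-49,,,17.9,62.2222222222222,0.43,10.6,meta,class_57-67
reference_sd,50-64,,,10.9,62.2222222222222,0.43,6.5,meta,class_57-67
c,40-49,,,18.6,75.6,0.459,1.157,station,class_67-83_dance
c,40-49,,,12.6,75.6,0.459,1.193,station,class_67-83_volpara
c,50-64,,,9.2,75.6,0.459,1.214,station,class_67-83_dance
c,50-64,,,9.6,75.6,0.459,1.212,station,class_67-83_volpara
reference_sd,40-49,,,12.6,75.6,0.459,8.2,meta,class_67-83
reference_sd,50-64,,,9.6,75.6,0.459,6.3,meta,class_67-83
c,40-49,,,6.2,95,0.459,1.249,station,class_>83_dance
c,40-49,,,9.8,95,0.459,1.223,station,class_>83_volpara
c,50-64,,,3.5,95,0.459,1.27,station,class_>83_dance
c,50-64,,,9.4,95,0.459,1.226,station,class_>83_volpara
reference_sd,40-49,,,9.8,95,0.459,9.4,meta,class_>83
reference_sd,50-64,,,9.4,95,0.459,7.4,meta,class_>83
glandularity,50-64,,,NA,20,NA,100,grid,published_grid
glandularity,50-64,,,NA,30,NA,72,grid,published_grid
glandularity,50-64,,,NA,40,NA,50,grid,published_grid
glandularity,50-64,,,NA,50,NA,33,grid,published_grid
glandularity,50-64,,,NA,60,NA,21,grid,published_grid
glandularity,50-64,,,NA,70,NA,12,grid,published_grid
glandularity,50-64,,,NA,80,NA,7,grid,published_grid
glandularity,50-64,,,NA,90,NA,4,grid,published_grid
glandularity,50-64,,,NA,100,NA,3,grid,published_grid
glandularity,50-64,,,NA,110,NA,3,grid,published_grid
glandularity,40-49,,,NA,23.1785714285714,NA,94.4,grid,class_<26
glandularity,40-49,,,NA,32.5454545454545,NA,77.4,grid,class_26-39
glandularity,40-49,,,NA,44.1764705882353,NA,58.3,grid,class_39-50
glandularity,40-49,,,NA,53.25,NA,44.8,grid,class_50-57
glandularity,40-49,,,NA,62.2222222222222,NA,32.9,grid,class_57-67
glandularity,40-49,,,NA,75.6,NA,18.6,grid,class_67-83
glandularity,40-49,,,NA,95,NA,6.2,grid,class_>83
s,,Mo,Mo,NA,NA,NA,1,grid,definitional
s,,Mo,Rh,NA,NA,NA,1.017,grid,published_s_factors
s,,Rh,Rh,NA,NA,NA,1.061,grid,published_s_factors
s,,Rh,Al,NA,NA,NA,1.044,grid,published_s_factors
s,,W,Rh,NA,NA,NA,1.042,grid,published_s_factors
s,,W,Ag,NA,NA,NA,1.042,grid,published_s_factors
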