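table,variable,comparison,level1,mean1,sd1,level2,mean2,sd2,printed_p,printed_d
1,trprv_s,group_post,CG_post,0.572,0.085,VG_post,0.517,0.075,0.010,0.69
1,trprv_s,group_pre,CG_pre,0.544,0.085,VG_pre,0.535,0.080,NA,NA
1,fsd_m,group_post,CG_post,0.336,0.150,VG_post,0.490,0.247,0.008,0.75
1,fsd_m,group_pre,CG_pre,0.313,0.210,VG_pre,0.426,0.210,NA,NA
1,dblpp_ratio,group_post,CG_post,0.754,0.144,VG_post,0.799,0.145,NA,NA
1,dblpp_ratio,group_pre,CG_pre,0.728,0.140,VG_pre,0.784,0.162,NA,NA
1,fda_deg,group_post,CG_post,12.064,6.102,VG_post,15.708,6.791,0.035,0.56
1,fda_deg,group_pre,CG_pre,13.710,6.706,VG_pre,15.037,6.973,NA,NA
2,trprv_s,laterality,DLL,0.538,0.080,NDLL,0.546,0.086,0.583,NA
2,fsd_m,laterality,DLL,0.343,0.181,NDLL,0.439,0.239,0.009,0.45
2,fda_deg,laterality,DLL,12.998,6.686,NDLL,15.262,6.607,0.051,NA
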