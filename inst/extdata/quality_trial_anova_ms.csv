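trait,units,entry_min,entry_max,entry_mean,ms_year,ms_genotype,ms_gxy,ms_error
Aroma,1-7 scale,3.10,5.20,4.0,4.72,1.57,1.23,1.24
Flavor,1-7 scale,3.10,5.20,4.0,10.47,1.75,1.06,1.28
Texture_Crumb,1-7 scale,2.70,5.10,3.70,7.04,2.47,1.11,1.17
Texture_Crust,1-7 scale,3.20,5.10,4.10,1.58,2.17,1.13,1.07
Grain_Protein_Concentration,%,9.12,14.64,11.27,12.43,1.67,1.19,0.09
Kernel_Hardness,%,7.32,31.12,19.36,40.22,30.20,24.02,2.72
SDS_Sedimentation_Volume,cm3,4.75,15.25,9.25,1548.39,5.71,2.69,0.17
Loaf_Volume,cm3,400,625,502,3517.66,1875.86,NA,602.08
Loaf_Density,g/cm3,0.41,0.74,0.53,6.15e-7,0.0021,NA,0.002
Loaf_Height,cm,5.4,8.9,6.9,2.73,0.33,NA,0.20
Dough_Extensibility,1-7 scale,1.00,7.00,3.30,35.03,3.31,NA,2.15
Flour_Protein_Concentration,%,8.28,15.07,10.87,NA,0.93,NA,0.76
T_HMW_GS,A%,21.33,31.59,26.46,NA,5.18,NA,0.79
T_LMW_GS,A%,10.21,16.03,13.06,NA,0.98,NA,0.18
T_Gli,A%,35.35,45.14,39.34,NA,5.85,NA,1.18
T_HMW_LMW,ratio,1.50,2.44,2.04,NA,0.02,NA,0.01
T_Gli_Glu,ratio,0.79,1.36,1.00,NA,0.02,NA,0.002
UPP_TPP,ratio,0.34,0.59,0.47,NA,0.002,NA,0.001
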