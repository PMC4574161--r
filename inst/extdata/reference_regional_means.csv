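region,region_name,n_species,n_pops,z_mean,z_sd,h_mean,h_sd,h_significant,fish_species,fish_pops,fish_mean,fish_sd,fish_significant,mollusc_species,mollusc_pops,mollusc_mean,mollusc_sd,mollusc_significant
25,Gulf of Carpentaria,17,52,0.146,0.127,0.249,0.139,FALSE,9,33,0.418,0.221,TRUE,NA,NA,NA,NA,NA
26,Joseph Bonaparte Gulf,11,21,0.138,0.135,0.584,0.204,TRUE,7,16,0.525,0.270,TRUE,1,2,-2.286,0.626,TRUE
27,NW coastal,17,46,-0.154,0.137,0.294,0.144,TRUE,8,18,0.092,0.238,FALSE,2,11,-2.130,0.437,TRUE
28,CW coastal transition,6,5,-0.089,0.145,0.406,0.283,FALSE,2,3,0.224,0.272,FALSE,NA,NA,NA,NA,NA
29,CW coastal,5,17,0.070,0.132,0.547,0.259,TRUE,2,2,0.150,0.350,FALSE,NA,NA,NA,NA,NA
30,SW coastal transition,5,16,-0.005,0.134,-0.172,0.207,FALSE,3,3,-0.248,0.320,FALSE,NA,NA,NA,NA,NA
31,SW coastal,11,40,-0.104,0.112,-0.280,0.160,FALSE,3,11,-0.547,0.299,TRUE,1,1,-0.390,0.633,FALSE
32,Great Australian Bight,7,15,0.048,0.127,-0.524,0.318,FALSE,3,3,-0.034,0.332,FALSE,1,1,0.199,0.565,FALSE
33,Spencer Gulf,15,59,-0.062,0.095,-0.125,0.132,FALSE,4,10,-0.407,0.274,FALSE,3,13,1.132,0.309,TRUE
34,W Bass Strait,11,41,0.088,0.105,0.126,0.151,FALSE,4,10,0.095,0.240,FALSE,2,22,1.768,0.325,TRUE
35,Bass Strait coastal,14,39,-0.056,0.109,-0.181,0.151,FALSE,7,19,-0.391,0.234,FALSE,3,10,0.987,0.326,TRUE
36,Tasmania coastal,13,79,-0.069,0.097,-0.246,0.131,FALSE,6,17,-0.324,0.230,FALSE,2,50,0.742,0.260,TRUE
37,SE coastal,25,105,0.075,0.095,-0.120,0.115,FALSE,12,47,0.160,0.191,FALSE,2,11,0.120,0.269,FALSE
38,Central NSW coastal,23,102,0.048,0.080,-0.127,0.116,FALSE,9,23,0.351,0.228,FALSE,3,16,-0.060,0.285,FALSE
39,Southern Qld / N NSW,25,67,-0.053,0.093,-0.268,0.130,TRUE,11,22,-0.041,0.190,FALSE,2,7,-0.241,0.366,FALSE
40,Southern GBR,47,212,-0.010,0.072,-0.136,0.097,FALSE,23,58,-0.230,0.184,FALSE,2,3,0.018,0.382,FALSE
41,Northern GBR,18,43,-0.011,0.097,-0.027,0.146,FALSE,4,4,0.208,0.288,FALSE,1,1,0.140,0.526,FALSE
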