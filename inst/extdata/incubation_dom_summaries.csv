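# Intensity-weighted SPE-DOM summary characteristics of the plume endmember
# and the per-Fe-level section datasets (formulae present in all retained
# replicates of a level) from the same incubation experiment as
# incubation_chemistry.csv. ideg on raw intensities of the full dataset;
# df_* are Rao's-entropy functional diversities. NEqPIW is a deep-sea
# reference SPE-DOM standard measured alongside.
sample,mz,h_c,o_c,aimod,dbe,nosc,ideg,n_form,df_c,df_hc,df_nosc,n_fe_form
Plume,407,1.28,0.45,0.237,8.13,-0.34,0.76,1722,2.19,0.080,0.160,94
Control section,267,1.43,0.30,0.245,5.20,-0.75,NA,317,2.64,0.185,0.269,7
0 uM Fe section,414,1.27,0.46,0.235,8.28,-0.31,0.80,1794,2.18,0.083,0.168,117
0.1 uM Fe section,411,1.28,0.46,0.236,8.22,-0.32,0.79,1741,2.20,0.082,0.166,98
1 uM Fe section,394,1.28,0.44,0.244,7.97,-0.38,0.74,1403,2.29,0.081,0.157,28
10 uM Fe section,372,1.30,0.41,0.255,7.60,-0.45,0.67,1197,2.43,0.093,0.162,11
100 uM Fe section,381,1.29,0.42,0.250,7.76,-0.42,0.69,1309,2.37,0.087,0.158,14
10 mM Fe section,357,1.30,0.39,0.263,7.38,-0.50,0.61,1172,2.54,0.101,0.167,8
NEqPIW section,424,1.28,0.45,0.235,8.42,-0.33,0.84,1527,2.30,0.079,0.158,NA
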