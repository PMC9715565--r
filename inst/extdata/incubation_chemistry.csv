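# Measured scalar chemistry of a hydrothermal-plume Fe-amendment incubation
# experiment (concentrations in umol/L; fe_nominal in umol/L of spiked Fe).
# role: plume = undiluted plume endmember, control = artificial-seawater
# control replicate, incubation = 7-day Fe-amended incubation.
# ligand_excess is L' = L - dFe where measured; empty where not determined.
# flag: star = control replicate excluded as dFe outlier; dagger = SPE-TDN
# exceeds TDN (contaminated extract).
sample,role,fe_nominal,replicate,dfe,ligand_excess,doc,spe_doc,tdn,spe_tdn,flag
Plume,plume,NA,1,0.071,0.143,75,20,35.2,0.9,
Control I,control,0,1,0.691,NA,786,10,502.4,0.7,star
Control II,control,0,2,0.295,0.029,849,8,489.5,0.3,
Control III,control,0,3,0.302,NA,973,6,498.1,0.6,
Inc 0 uM Fe I,incubation,0,1,0.225,0.196,368,24,4.2,1.2,
Inc 0 uM Fe II,incubation,0,2,0.137,NA,511,18,4.4,2.0,
Inc 0 uM Fe III,incubation,0,3,0.257,NA,577,28,5.3,1.2,
Inc 0.1 uM Fe I,incubation,0.1,1,0.201,0.230,339,29,7.1,1.3,
Inc 0.1 uM Fe II,incubation,0.1,2,0.149,NA,420,26,2.4,1.0,
Inc 0.1 uM Fe III,incubation,0.1,3,0.144,NA,471,34,2.9,6.7,dagger
Inc 1 uM Fe I,incubation,1,1,0.96,2.13,467,28,4.7,0.8,
Inc 1 uM Fe II,incubation,1,2,1.14,NA,318,23,2.7,1.3,
Inc 1 uM Fe III,incubation,1,3,0.89,NA,926,25,3.0,1.2,
Inc 10 uM Fe I,incubation,10,1,9.9,NA,511,20,2.5,2.6,dagger
Inc 10 uM Fe II,incubation,10,2,10.0,NA,671,28,4.0,1.0,
Inc 10 uM Fe III,incubation,10,3,10.7,16.3,389,30,1.7,1.2,
Inc 100 uM Fe I,incubation,100,1,95.0,NA,394,28,2.1,2.4,dagger
Inc 100 uM Fe II,incubation,100,2,107,132,677,25,2.9,1.3,
Inc 100 uM Fe III,incubation,100,3,103,NA,1030,27,4.1,1.2,
Inc 1 mM Fe I,incubation,1000,1,975,NA,886,20,2.9,0.9,lowseq
Inc 1 mM Fe II,incubation,1000,2,1000,2918,842,23,52.3,1.2,lowseq
Inc 10 mM Fe I,incubation,10000,1,10291,NA,648,35,3.0,1.6,
Inc 10 mM Fe II,incubation,10000,2,10273,NA,668,28,2.5,1.1,
Inc 10 mM Fe III,incubation,10000,3,10399,NA,702,22,3.0,0.9,
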