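"variable","phenotype","marker","comparison","target","lo","hi","units"
"basal-cAMP","basal","cAMP","absolute",0.06,NA,NA,"uM"
"basal-STEPact","basal","STEPact","absolute",0.8,NA,NA,"fraction"
"basal-D32p34","basal","D32p34","absolute",0.35,0.2,0.5,"uM"
"basal-D32p75","basal","D32p75","absolute",13,NA,NA,"uM"
"DAslice-D32p34","DAslice","D32p34","fold-over-basal",12,NA,NA,"fold"
"DAslice-D32p75","DAslice","D32p75","fold-over-basal",0.5,NA,NA,"fold"
"NMDAslice-D32p34","NMDAslice","D32p34","fold-over-basal",0.5,NA,NA,"fold"
"NMDAslice-D32p75","NMDAslice","D32p75","fold-over-basal",0.5,NA,NA,"fold"
"activateRAS-h","activateRAS","RASRAF_fraction","fitted-parameter",4.1,NA,NA,""
"activateRAS-K","activateRAS","RASRAF_fraction","fitted-parameter",0.8,NA,NA,"uM"
"trafficNMDAR-k","trafficNMDAR","NMDAR_current_scale","fitted-parameter",0.15,NA,NA,"min^-1"
"haploD1R-ERKpp","haploD1R","ERKpp","ratio-to-WT",0.5,NA,NA,"x WT"
"haploD1R-GluR1p","haploD1R","GluR1p845","ratio-to-WT",1,NA,NA,"x WT"
"haploGolf-ERKpp","haploGolf","ERKpp","ratio-to-WT",0.9,NA,NA,"x WT"
"haploGolf-GluR1p","haploGolf","GluR1p845","ratio-to-WT",0.6,NA,NA,"x WT"
"D32KO-ERKpp","D32KO","ERKpp","ratio-to-WT",0.4,NA,NA,"x WT"
"D32KO-GluR1p","D32KO","GluR1p845","ratio-to-WT",0.35,NA,NA,"x WT"
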