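model,histology,median_control_days,median_treated_days,treated_median_reached,activity
NCH-RBD2,Extrarenal,15.2,49.5,TRUE,MCR
Rh-18,Extrarenal,17.3,83.8,TRUE,CR
WT-16,RTK,36.3,161,FALSE,MCR
NCH-RBD1,Extrarenal,126.6,31.7,TRUE,PR
BT-29,AT/RT,10.2,34.9,TRUE,PR
G401,RTK,13.3,17.8,TRUE,PD
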