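model,arm,n,km_median,efs_t_minus_c,efs_t_over_c,med_resp
COG-N-415X,vehicle,3,8.61,,,PD
COG-N-415X,treated,3,20.62,12.01,2.39,PD2
COG-N-421X,vehicle,3,18.52,,,PD
COG-N-421X,treated,3,104.32,85.8,5.63,MCR
COG-N-424X,vehicle,3,8.38,,,PD
COG-N-424X,treated,3,>84,75.62,10.02,MCR
COG-N-453X,vehicle,3,7.85,,,PD
COG-N-453X,treated,3,44.65,36.8,5.69,PD2
COG-N-519X,vehicle,3,14.23,,,PD
COG-N-519X,treated,3,88.66,74.43,6.23,CR
COG-N-557X,vehicle,3,26.6,,,PD
COG-N-557X,treated,3,74.45,47.85,2.8,PD2
COG-N-561X,vehicle,3,12.98,,,PD
COG-N-561X,treated,3,80.88,67.9,6.23,CR
COG-N-619X,vehicle,3,22.62,,,PD
COG-N-619X,treated,3,45.49,22.87,2.01,PD2
FELIX-PDX,vehicle,3,13.17,,,PD
FELIX-PDX,treated,3,77.29,64.12,5.87,CR
NB-EBC1,vehicle,3,4.54,,,PD
NB-EBC1,treated,3,80.11,75.57,17.65,CR
6FN,vehicle,3,14.32,,,PD
6FN,treated,3,22.36,8.04,1.56,PD1
NB-SD,vehicle,3,12.64,,,PD
NB-SD,treated,3,91.73,79.09,7.26,PR
NB-1643,vehicle,3,6.13,,,PD
NB-1643,treated,3,96.43,90.3,15.73,CR
NB-1691,vehicle,3,8.3,,,PD
NB-1691,treated,3,79.77,71.47,9.61,PD2
SK-N-AS,vehicle,3,13.74,,,PD
SK-N-AS,treated,3,64.85,51.11,4.72,PD2
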