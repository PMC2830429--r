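endpoint,year,age_group,value,role
EAC_INCIDENCE,1986,20-29,0,CALIBRATION
BE_PREV,ALL,20-29,1.7,CALIBRATION
GERD_PREV,ALL,20-29,17.6,CALIBRATION
EAC_INCIDENCE,1986,30-39,0.3,CALIBRATION
BE_PREV,ALL,30-39,2.5,CALIBRATION
GERD_PREV,ALL,30-39,18,CALIBRATION
EAC_INCIDENCE,1986,40-49,0.6,CALIBRATION
BE_PREV,ALL,40-49,3.3,CALIBRATION
GERD_PREV,ALL,40-49,18.4,CALIBRATION
EAC_INCIDENCE,1986,50-59,3.3,CALIBRATION
BE_PREV,ALL,50-59,4.1,CALIBRATION
GERD_PREV,ALL,50-59,18.8,CALIBRATION
EAC_INCIDENCE,1986,60-69,7.4,CALIBRATION
BE_PREV,ALL,60-69,5,CALIBRATION
GERD_PREV,ALL,60-69,19.1,CALIBRATION
EAC_INCIDENCE,1986,70-79,9.3,CALIBRATION
BE_PREV,ALL,70-79,5.8,CALIBRATION
GERD_PREV,ALL,70-79,19.5,CALIBRATION
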