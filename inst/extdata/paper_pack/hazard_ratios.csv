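block,prior,event,hr,lo,hi
no_treatment,NA,OMB,1.24,0.70,2.26
no_treatment,NA,CRNMB,1.24,0.70,2.26
no_treatment,NA,MI,0.44,0.20,1.03
no_treatment,NA,IS,0.26,0.18,0.37
no_treatment,NA,ICH,1.90,0.64,6.49
no_treatment,NA,REV,0.44,0.20,1.03
no_treatment,NA,SE,0.26,0.18,0.37
aging,NA,OMB,1.97,1.79,2.16
aging,NA,MI,1.30,0.74,2.01
aging,NA,IS,1.46,0.80,2.16
aging,NA,ICH,1.97,1.79,2.16
subsequent,OMB,ICH,3.54,3.02,4.17
subsequent,OMB,OMB,3.32,3.06,3.60
subsequent,OMB,MI,1.00,NA,NA
subsequent,OMB,IS,1.32,1.21,1.44
subsequent,MI,ICH,1.00,NA,NA
subsequent,MI,OMB,1.00,NA,NA
subsequent,MI,MI,1.00,NA,NA
subsequent,MI,IS,1.00,NA,NA
subsequent,IS,ICH,1.64,1.39,1.94
subsequent,IS,OMB,1.39,1.27,1.52
subsequent,IS,MI,1.00,NA,NA
subsequent,IS,IS,4.00,3.78,4.22
subsequent,ICH,ICH,10.20,8.59,12.20
subsequent,ICH,OMB,2.95,2.57,3.39
subsequent,ICH,MI,1.00,NA,NA
subsequent,ICH,IS,1.78,1.56,2.03
postacute_mortality,NA,event_free,1.16,1.10,1.22
postacute_mortality,NA,MI,1.45,1.38,1.53
postacute_mortality,NA,IS,2.60,2.30,3.00
postacute_mortality,NA,ICH,2.20,NA,NA
postacute_mortality,NA,OMB,1.16,1.10,1.22
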