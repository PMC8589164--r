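event,period,mean_event,se_event,mean_control,se_control,ratio
OMB,acute,0.808,0.014,0.837,0.001,0.965
CRNMB,acute,0.826,0.007,0.836,0.002,0.988
MI,acute,0.690,0.011,0.805,0.081,0.857
IS,acute,0.640,0.016,0.830,0.012,0.771
ICH,acute,0.560,0.077,0.830,0.012,0.675
REV,acute,0.780,0.016,0.800,0.012,0.975
SE,acute,0.730,0.014,0.830,0.012,0.879
OMB,post_acute,0.829,0.083,0.837,0.001,0.990
MI,post_acute,0.702,0.006,0.799,0.080,0.878
IS,post_acute,0.685,0.008,0.830,0.012,0.825
ICH,post_acute,0.705,0.044,0.830,0.012,0.849
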