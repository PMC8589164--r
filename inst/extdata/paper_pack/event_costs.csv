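event,acute,maintenance_monthly,societal_acute,societal_monthly
OMB,3341.59,0.00,0.00,0.00
CRNMB,2412.85,0.00,0.00,0.00
MI,4153.47,168.12,0.00,0.00
IS,5094.95,1494.37,516.37,1610.38
ICH,5987.77,1494.37,516.37,1610.38
REV,15599.15,0.00,0.00,0.00
SE,3875.89,0.00,0.00,0.00
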