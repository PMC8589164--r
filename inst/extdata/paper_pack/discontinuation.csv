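kind,key,prob,se
event,OMB,0.250,0.0250
event,ICH,0.558,0.0689
event,MI,0.000,NA
event,IS,0.000,NA
unrelated,apixaban,0.0454,0.0045
unrelated,vka,0.0480,0.0048
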