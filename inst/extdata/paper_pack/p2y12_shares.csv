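arm,clopidogrel,prasugrel,ticagrelor
apixaban,0.934,0.012,0.054
vka,0.918,0.011,0.071
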