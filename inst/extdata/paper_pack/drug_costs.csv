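agent,price_per_mg,daily_dose_mg,cost_per_cycle
apixaban,0.19,10,173.49
acenocoumarol,0.03,5,13.70
warfarin,0.02,5,9.13125
aspirin,0.00,81,3.58
clopidogrel,0.01,75,54.82
prasugrel,0.07,10,63.92
ticagrelor,0.02,120,194.81
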