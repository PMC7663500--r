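# Li-Ion polymer battery powering the eyeglasses
kind: battery
name: Li-Ion polymer battery
V: 3.7
capacity_mWh: 925
runtime_h: 16
derating: 0.9
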