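# Bipolar surface-EMG sensing front-end
kind: sensor
name: EMG sensing
I_act_mA: 4.0
I_stb_mA: 0.008
V: 3.3
rate_hz: 256
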