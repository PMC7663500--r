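# BLE radio at 0 dBm transmit power
kind: radio
name: BLE radio
I_trans_mA: 21.7
t_trans_ms: 16
packet_bytes: 114
mps_bits: 216
conn_interval_min_ms: 7.5
conn_interval_max_ms: 4000
conn_interval_step_ms: 1.25
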