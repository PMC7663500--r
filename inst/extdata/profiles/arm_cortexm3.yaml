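# ARM CortexM3 microcontroller profile (datasheet-derived values)
kind: mcu
name: ARM CortexM3
cycles:
  add: 60
  mult: 50
  div: 80
  root: 380
  comp: 12
  exp: 210
clock_mhz: 48
I_act_mA: 7.0
I_stb_mA: 0.55
V: 3.3
resolution_bits: 32
flash_kB: 512
ram_kB: 96
block_bytes: 256
I_write_uA: 500
t_write_ms: 3.28
I_stb_mem_mA: 0.0
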