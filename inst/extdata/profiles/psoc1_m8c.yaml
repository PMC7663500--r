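# PSoC1 M8C microcontroller profile (datasheet-derived values)
kind: mcu
name: PSoC1 M8C
cycles:
  add: 544
  mult: 560
  div: 912
  root: 1344
  comp: 80
  exp: 2672
clock_mhz: 24
I_act_mA: 8.0
I_stb_mA: 0.025
V: 3.3
resolution_bits: 8
flash_kB: 32
ram_kB: 2
block_bytes: 64
I_write_uA: 619.5
t_write_ms: 1.5
I_stb_mem_mA: 0.0
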