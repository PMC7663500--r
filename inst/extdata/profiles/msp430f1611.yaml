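# TI MSP430F1611 microcontroller profile (datasheet-derived values)
kind: mcu
name: TI MSP430F1611
cycles:
  add: 177
  mult: 153
  div: 405
  root: 668
  comp: 37
  exp: 334
clock_mhz: 8
I_act_mA: 0.57
I_stb_mA: 0.05
V: 3.0
resolution_bits: 16
flash_kB: 48.25
ram_kB: 10
block_bytes: 60
I_write_uA: 2300
t_write_ms: 23.0
I_stb_mem_mA: 0.0
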