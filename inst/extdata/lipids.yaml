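# Species constants: molecular weight (g/mol) and hydrophobic tail volume
# (nm^3/molecule). Mixture: 9:1 PG/LPG by mole.
species:
  - {name: PG,  mw: 782, v_tail: 0.96}
  - {name: LPG, mw: 506, v_tail: 0.46}
  - {name: PC,  mw: 770, v_tail: 0.96}
mixture:
  - {name: PG,  fraction: 0.9}
  - {name: LPG, fraction: 0.1}
flow:
  t_start: 5
  t_rinse: 45
  t_end: 55
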