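# Conventional (steady-state) SPGR variable-flip-angle phantom protocol.
# No preparation blocks: with T_FS = T_BS = T_Sp = 0 the I-SPGR model
# collapses to the Ernst equation, so k is irrelevant and set to 1.
name: phantom_spgr
TR: 6.6
TE: 1.2
k: 1
T_FS: 0
measurements:
  - {alpha: 25, T_BS: 0, T_Sp: 0}
  - {alpha: 20, T_BS: 0, T_Sp: 0}
  - {alpha: 15, T_BS: 0, T_Sp: 0}
  - {alpha: 10, T_BS: 0, T_Sp: 0}
  - {alpha: 5,  T_BS: 0, T_Sp: 0}
  - {alpha: 2,  T_BS: 0, T_Sp: 0}
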