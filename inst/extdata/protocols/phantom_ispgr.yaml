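# Phantom blood- and fat-suppressed I-SPGR variable-flip-angle protocol.
# The fat-suppression duration was lengthened relative to the in-vivo scan so
# that the total shot length matched despite the longer TR
# (110 + 30 x 6.6 ~= 202 + 30 x 3.5). See invivo_ispgr.yaml for the
# column-assignment caveat.
name: phantom_ispgr
TR: 6.6
TE: 1.2
k: 30
T_FS: 110
T_FS_alternative: 202
measurements:
  - {alpha: 25, T_BS: 13, T_Sp: 10}
  - {alpha: 20, T_BS: 13, T_Sp: 10}
  - {alpha: 10, T_BS: 13, T_Sp: 10}
  - {alpha: 4,  T_BS: 13, T_Sp: 10}
  - {alpha: 10, T_BS: 20, T_Sp: 14}
  - {alpha: 10, T_BS: 35, T_Sp: 21}
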