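# In-vivo blood- and fat-suppressed I-SPGR variable-flip-angle protocol.
# Times in ms, flip angles in degrees. TE is metadata only (not modeled).
name: invivo_ispgr
TR: 3.5
TE: 1.2
k: 30
T_FS: 202
# Alternative fat-suppression duration: the protocol table prints 110 ms and
# 202 ms for the phantom and in-vivo I-SPGR scans with an ambiguous column
# assignment; the shot-length-matching footnote supports 202 ms in vivo.
T_FS_alternative: 110
measurements:
  - {alpha: 25, T_BS: 13, T_Sp: 10}
  - {alpha: 20, T_BS: 13, T_Sp: 10}
  - {alpha: 10, T_BS: 13, T_Sp: 10}
  - {alpha: 4,  T_BS: 13, T_Sp: 10}
  - {alpha: 10, T_BS: 20, T_Sp: 14}
  - {alpha: 10, T_BS: 35, T_Sp: 21}
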