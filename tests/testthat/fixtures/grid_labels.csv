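label
boar+wolf_T0_L0
boar+wolf_T0_L0.5
boar+wolf_T0_L1
boar+wolf_T0.5_L0
boar+wolf_T0.5_L0.5
boar+wolf_T0.5_L1
boar+wolf_T1_L0
boar+wolf_T1_L0.5
boar+wolf_T1_L1
wolf-only_T0_L0
wolf-only_T0_L0.5
wolf-only_T0_L1
wolf-only_T0.5_L0
wolf-only_T0.5_L0.5
wolf-only_T0.5_L1
wolf-only_T1_L0
wolf-only_T1_L0.5
wolf-only_T1_L1
boar-only_T0_L0
boar-only_T0_L0.5
boar-only_T0_L1
boar-only_T0.5_L0
boar-only_T0.5_L0.5
boar-only_T0.5_L1
boar-only_T1_L0
boar-only_T1_L0.5
boar-only_T1_L1
neither_T0_L0
neither_T0_L0.5
neither_T0_L1
neither_T0.5_L0
neither_T0.5_L0.5
neither_T0.5_L1
neither_T1_L0
neither_T1_L0.5
neither_T1_L1
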