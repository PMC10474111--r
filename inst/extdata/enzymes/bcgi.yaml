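# BcgI, REBASE geometry (10/12)CGANNNNNNTGC(12/10).
name: BcgI
recognition: CGANNNNNNTGC
left_flank: 12
right_flank: 12
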