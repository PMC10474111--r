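# CjePI, REBASE geometry (7/13)CCANNNNNNNTC(14/8).
# The in-silico window spans the full double-stranded fragment:
# max flank on each side of the recognition site.
name: CjePI
recognition: CCANNNNNNNTC
left_flank: 13
right_flank: 14
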