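# Gene symbol aliases: legacy or alternate symbol -> canonical symbol.
# Extend with additional rows as needed.
alias	canonical
MLL2	KMT2D
MLL4	KMT2B
MLL	KMT2A
MLL3	KMT2C
EVI1	MECOM
PRKDC1	PRKDC
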