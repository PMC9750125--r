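# default clock and clock-associated gene set (17 genes); edit freely
ARNTL
NPAS2
CLOCK
NFIL3
CRY1
CRY2
PER1
PER2
PER3
NR1D1
NR1D2
RORA
RORB
RORC
DBP
TEF
HLF
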