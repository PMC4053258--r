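SRC	pp	PDPK1
SRC	pp	IKBKB
SRC	pp	BCL2L1
SRC	pp	FGFR4
SRC	pp	BCR
SRC	pp	ACTN4
SRC	pp	PIP5K1C
SRC	pp	RIOK3
PDPK1	pp	IKBKB
PDPK1	pp	RPS6KB2
PDPK1	pp	PIP5K1C
PDPK1	pp	FGFR4
PDPK1	pp	BCR
PDPK1	pp	ATP5A1
PDPK1	pp	HIPK2
IKBKB	pp	BIRC2
IKBKB	pp	BIRC3
IKBKB	pp	MKNK1
IKBKB	pp	HIPK2
IKBKB	pp	ACTN4
IKBKB	pp	ATP5A1
BCL2L1	pp	BIRC2
BCL2L1	pp	BIRC3
BCL2L1	pp	BCL2L2
BCL2L1	pp	ATP5A1
BCL2L1	pp	BCR
BCL2L1	pp	HIPK2
BCL2L1	pp	MKNK1
BIRC2	pp	BIRC3
MKNK1	pp	RPS6KB2
NEK6	pp	PLK1
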