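gene,note
1L1B,probable typo for IL1B (interleukin-1 beta)
IL-18,hyphenated form; HGNC symbol is IL18
IL-33,hyphenated form; HGNC symbol is IL33
IL-6,hyphenated form; HGNC symbol is IL6
ABCBC1,not a recognized symbol; probably ABCB1 (P-glycoprotein)
LAMA,truncated laminin alpha family symbol (LAMA1-5); member unspecified
FCGR2A,paired with CD16 in the source; conventionally FCGR2A = CD32
FCGR3A,paired with CD32 in the source; conventionally FCGR3A = CD16
CXCL8,also printed as IL-8
CCL2,also printed as MCP-1
TNFRSF1A,also printed as TNFR1
MRC1,also printed as CD206
FCGR1A,also printed as CD64
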