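# Core promoter element definitions (human Pol II), TSS = position 0.
# Consensi and canonical windows transcribed from the standard human CPE
# compendium (Haberle & Stark 2018, Nat Rev Mol Cell Biol 19:621); positions
# converted from their +1 TSS convention to TSS = 0.
# columns: name consensus canonical_start max_shift source
name	consensus	canonical_start	max_shift	source
BREu	SSRCGCC	-38	5	upstream TFIIB recognition element, -38..-32
TATA	TATAWAWR	-31	5	TATA box, -31..-24
BREd	RTDKKKK	-23	5	downstream TFIIB recognition element, -23..-17
Inr	BBCABW	-3	5	initiator, A at the TSS (0), -3..+2
DPE	RGWYVT	27	5	downstream promoter element, +27..+32
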