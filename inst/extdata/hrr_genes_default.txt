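# Provisional 25-gene homologous-recombination-repair (HRR) panel.
# This default list is a commonly assayed HRR gene set; clinical panels
# differ, so supply your own one-symbol-per-line file where it matters.
ATM
ATR
BARD1
BLM
BRCA1
BRCA2
BRIP1
CDK12
CHEK1
CHEK2
FANCA
FANCC
FANCD2
FANCI
FANCL
MRE11A
NBN
PALB2
PPP2R2A
RAD50
RAD51
RAD51B
RAD51C
RAD51D
RAD54L
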