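# Starter catalogue of proteins routinely introduced by reagents or
# sample handling (keratins from skin/dust, serum albumin, trypsin
# used for digestion). Extend per experiment; immunoglobulin and
# hemoglobin families are matched by the anchored patterns configured
# in the analysis scripts.
KRT1
KRT2
KRT5
KRT6A
KRT9
KRT10
KRT14
KRT16
KRT17
ALB
TRY1
PRSS1
CASQ1
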