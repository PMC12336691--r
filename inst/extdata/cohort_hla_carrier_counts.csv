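cohort,n,nA,nB,nAB
ACP,309,101,136,60
BIONAT,1255,359,564,212
EPIC,178,57,98,35
FinBB,1049,515,489,265
NationMS,405,125,193,80
CombiRx,699,216,341,146
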