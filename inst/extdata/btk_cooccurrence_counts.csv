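gene,count,published_rank
TNF,49,10
CCL3,9,84
SDC1,4,186
IKZF1,3,241
IRF4,3,241
EGR1,1,684
RASGRP1,1,684
BCL2A1,0,7272
EBI3,0,7272
EGR3,0,7272
IGJ,0,7272
IGKC,0,7272
IL4I1,0,7272
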