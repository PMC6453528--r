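gene,rank
BCL2A1,2240
CCL3,506
EBI3,124
EGR1,384
EGR3,1448
IKZF1,379
IL4I1,2775
IRF4,284
RASGRP1,997
TNF,3
IGKC,10558
IGJ,9933
SDC1,654
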