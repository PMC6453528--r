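# Expert-curated candidate pharmacodynamic biomarkers for BTK inhibition
BCL2A1
CCL3
EBI3
EGR1
EGR3
IKZF1
IL4I1
IRF4
RASGRP1
TNF
IGKC
IGJ
SDC1
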