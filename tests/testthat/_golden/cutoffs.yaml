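source: learned
endpoint: os
tLNV: 106.6644045
tLND: 152.0150319
tLNV_statistic: 31.1251457
tLND_statistic: 39.2295881
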