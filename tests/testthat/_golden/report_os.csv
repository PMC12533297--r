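"subtype","n","events","five_year_survival"
"LRS",77,45,0.589913323926628
"MRS",137,115,0.259188851044429
"HRS",86,77,0.101793826067082
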