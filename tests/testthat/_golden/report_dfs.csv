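"subtype","n","events","five_year_survival"
"LRS",77,66,0.261799005582955
"MRS",137,130,0.0639022859021738
"HRS",86,81,NA
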