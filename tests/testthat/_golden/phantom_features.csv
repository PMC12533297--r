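"patient_id","tLNV","tLND","node_count","no_nodes","volume_mode"
"phantom-1235",86.2821125534466,73.1051699825952,3,FALSE,"accumulated"
"phantom-1236",167.601654023837,86.5946427345795,4,FALSE,"accumulated"
"phantom-1237",44.3368811568276,24.0578458747862,1,FALSE,"accumulated"
"phantom-1238",84.0803991074246,81.2782377738696,3,FALSE,"accumulated"
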