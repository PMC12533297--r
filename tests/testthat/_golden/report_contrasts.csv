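"endpoint","contrast","estimate","ci_lower","ci_upper","p"
"os","global_logrank",67.8529726733928,NA,NA,1.84465092345877e-15
"os","MRS_vs_LRS",2.51729632640059,1.77040873029881,3.57927561385238,2.73665723460254e-07
"os","HRS_vs_LRS",4.68265105805114,3.18104221556315,6.89309334663626,5.04129815377062e-15
"dfs","global_logrank",50.7895136869733,NA,NA,9.35830582441707e-12
"dfs","MRS_vs_LRS",1.99791599429458,1.4760993185398,2.70420036790396,7.41858550142631e-06
"dfs","HRS_vs_LRS",3.40952477732941,2.4072964944377,4.82901015063312,4.95721873389656e-12
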