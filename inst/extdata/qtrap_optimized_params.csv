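precursor_mz,fragment,dp,ce
733.33,y8,85,38.3
733.33,y7,85,38.3
733.33,y5,85,38.3
735.84,y8,85,38.3
735.84,y7,85,38.3
735.84,y5,85,38.3
622.34,b14,80,27.9
622.34,b15,80,26.4
624.68,b14,80,27.9
624.68,b15,80,26.4
467.01,b13,70,21.7
467.01,b14,70,17.2
468.76,b13,70,21.7
468.76,b14,70,17.2
580.65,y7,85,29.6
580.65,y6,85,31.1
580.65,y5,85,31.1
582.99,y7,85,29.6
582.99,y6,85,31.1
582.99,y5,85,31.1
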