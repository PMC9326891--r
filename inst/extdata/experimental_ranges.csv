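species,low_V,high_V,source_tag
A,1.20,1.63,literature_compilation
C,1.44,1.86,literature_compilation
G,0.80,1.53,literature_compilation
T,1.29,1.73,literature_compilation
U,1.34,1.75,literature_compilation
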