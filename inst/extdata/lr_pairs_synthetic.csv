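ligand,receptor,source
LIG01,REC01,synthetic
LIG02,REC02,synthetic
LIG03,REC03,synthetic
LIG04,REC04,synthetic
LIG05,REC05,synthetic
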