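{"name": "SacI", "recognition": "GAGCTC", "cut_offset": 5}
{"name": "HinfI", "recognition": "GANTC", "cut_offset": 1}
{"name": "EcoRI", "recognition": "GAATTC", "cut_offset": 1}
{"name": "BamHI", "recognition": "GGATCC", "cut_offset": 1}
{"name": "HindIII", "recognition": "AAGCTT", "cut_offset": 1}
{"name": "EcoRV", "recognition": "GATATC", "cut_offset": 3}
{"name": "DraI", "recognition": "TTTAAA", "cut_offset": 3}
{"name": "PstI", "recognition": "CTGCAG", "cut_offset": 5}
{"name": "KpnI", "recognition": "GGTACC", "cut_offset": 5}
{"name": "AluI", "recognition": "AGCT", "cut_offset": 2}
{"name": "RsaI", "recognition": "GTAC", "cut_offset": 2}
{"name": "HaeIII", "recognition": "GGCC", "cut_offset": 2}
{"name": "TaqI", "recognition": "TCGA", "cut_offset": 1}
{"name": "MseI", "recognition": "TTAA", "cut_offset": 1}
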