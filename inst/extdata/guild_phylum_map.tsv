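phylum	guild
Proteobacteria	copiotroph
Actinobacteria	copiotroph
Firmicutes	copiotroph
Bacteroidetes	copiotroph
Acidobacteria	oligotroph
Verrucomicrobia	oligotroph
Chloroflexi	oligotroph
Planctomycetes	oligotroph
Gemmatimonadetes	oligotroph
Nitrospirae	oligotroph
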