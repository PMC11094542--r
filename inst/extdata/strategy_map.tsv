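phylum	strategy
Proteobacteria	copiotroph
Bacteroidota	copiotroph
Firmicutes	copiotroph
Actinobacteriota	copiotroph
Acidobacteriota	oligotroph
Chloroflexi	oligotroph
Verrucomicrobiota	oligotroph
Planctomycetota	oligotroph
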