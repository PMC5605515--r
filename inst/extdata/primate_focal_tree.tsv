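branch	parent
Euarchontoglires	NA
Euarchonta	Euarchontoglires
Glires	Euarchontoglires
Primatomorpha	Euarchonta
Dermoptera	Primatomorpha
Primates	Primatomorpha
Strepsirrhini	Primates
Haplorrhini	Primates
Tarsiidae	Haplorrhini
Simiiformes	Haplorrhini
Cebidae-stem	Simiiformes
Aotus	Cebidae-stem
Catarrhini	Simiiformes
Cercopithecidae	Catarrhini
Hominoidae	Catarrhini
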