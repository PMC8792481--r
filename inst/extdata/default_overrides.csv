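exporter,importer,year_min,year_max,class,citation
ZA,RW,2015,2017,W2,Akagera restocking documented in grey literature as sourced from the South African managed metapopulation
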