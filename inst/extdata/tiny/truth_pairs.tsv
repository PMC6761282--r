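mirna	gene
miR-01	gene-021
miR-02	gene-022
miR-03	gene-023
miR-04	gene-024
miR-05	gene-025
miR-06	gene-026
miR-07	gene-027
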