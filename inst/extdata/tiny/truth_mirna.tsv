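feature	direction	logfc
miR-01	+	2
miR-02	-	-2
miR-03	+	2
miR-04	-	-2
miR-05	+	2
miR-06	-	-2
miR-07	+	2
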