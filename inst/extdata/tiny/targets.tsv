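mirna	gene	source	evidence
miR-01	gene-021	synthetic	predicted
miR-01	gene-134	synthetic	predicted
miR-01	gene-274	synthetic	predicted
miR-01	gene-355	synthetic	predicted
miR-01	gene-375	synthetic	predicted
miR-01	gene-490	synthetic	predicted
miR-02	gene-022	synthetic	predicted
miR-02	gene-054	synthetic	predicted
miR-02	gene-062	synthetic	predicted
miR-02	gene-107	synthetic	predicted
miR-02	gene-225	synthetic	predicted
miR-02	gene-292	synthetic	predicted
miR-02	gene-293	synthetic	predicted
miR-02	gene-341	synthetic	predicted
miR-02	gene-380	synthetic	predicted
miR-02	gene-434	synthetic	predicted
miR-02	gene-449	synthetic	predicted
miR-03	gene-006	synthetic	predicted
miR-03	gene-023	synthetic	predicted
miR-03	gene-036	synthetic	predicted
miR-03	gene-085	synthetic	predicted
miR-03	gene-094	synthetic	predicted
miR-03	gene-099	synthetic	predicted
miR-03	gene-158	synthetic	predicted
miR-03	gene-163	synthetic	predicted
miR-03	gene-209	synthetic	predicted
miR-03	gene-279	synthetic	predicted
miR-03	gene-398	synthetic	predicted
miR-04	gene-024	synthetic	predicted
miR-04	gene-056	synthetic	predicted
miR-04	gene-220	synthetic	predicted
miR-04	gene-273	synthetic	predicted
miR-04	gene-378	synthetic	predicted
miR-04	gene-432	synthetic	predicted
miR-05	gene-025	synthetic	predicted
miR-05	gene-140	synthetic	predicted
miR-05	gene-159	synthetic	predicted
miR-05	gene-168	synthetic	predicted
miR-05	gene-199	synthetic	predicted
miR-05	gene-222	synthetic	predicted
miR-05	gene-250	synthetic	predicted
miR-05	gene-268	synthetic	predicted
miR-05	gene-338	synthetic	predicted
miR-05	gene-346	synthetic	predicted
miR-05	gene-386	synthetic	predicted
miR-05	gene-392	synthetic	predicted
miR-05	gene-473	synthetic	predicted
miR-05	gene-478	synthetic	predicted
miR-06	gene-026	synthetic	predicted
miR-06	gene-043	synthetic	predicted
miR-06	gene-055	synthetic	predicted
miR-06	gene-057	synthetic	predicted
miR-06	gene-098	synthetic	predicted
miR-06	gene-107	synthetic	predicted
miR-06	gene-116	synthetic	predicted
miR-06	gene-220	synthetic	predicted
miR-06	gene-253	synthetic	predicted
miR-06	gene-304	synthetic	predicted
miR-06	gene-331	synthetic	predicted
miR-06	gene-456	synthetic	predicted
miR-06	gene-474	synthetic	predicted
miR-07	gene-027	synthetic	predicted
miR-07	gene-040	synthetic	predicted
miR-07	gene-056	synthetic	predicted
miR-07	gene-133	synthetic	predicted
miR-07	gene-171	synthetic	predicted
miR-07	gene-214	synthetic	predicted
miR-07	gene-243	synthetic	predicted
miR-07	gene-269	synthetic	predicted
miR-07	gene-279	synthetic	predicted
miR-07	gene-322	synthetic	predicted
miR-07	gene-360	synthetic	predicted
miR-07	gene-375	synthetic	predicted
miR-07	gene-402	synthetic	predicted
miR-07	gene-404	synthetic	predicted
miR-07	gene-411	synthetic	predicted
miR-07	gene-422	synthetic	predicted
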