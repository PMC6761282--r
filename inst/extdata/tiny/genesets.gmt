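SET01	random synthetic set	gene-414	gene-148	gene-087	gene-024	gene-030	gene-364	gene-140	gene-119	gene-330	gene-068	gene-069	gene-135	gene-153	gene-327	gene-442	gene-446	gene-063	gene-309	gene-242	gene-470	gene-403	gene-353	gene-073	gene-236	gene-261
SET02	random synthetic set	gene-019	gene-061	gene-182	gene-500	gene-023	gene-007	gene-058	gene-183	gene-248	gene-220	gene-459	gene-276	gene-235	gene-115	gene-140	gene-161	gene-272	gene-344	gene-465	gene-116	gene-237	gene-083	gene-043	gene-026	gene-388
SET03	random synthetic set	gene-447	gene-091	gene-483	gene-225	gene-423	gene-277	gene-178	gene-372	gene-194	gene-075	gene-458	gene-149	gene-171	gene-408	gene-032	gene-070	gene-463	gene-142	gene-090	gene-117	gene-049	gene-001	gene-216	gene-092	gene-493
SET04	random synthetic set	gene-421	gene-410	gene-343	gene-477	gene-108	gene-500	gene-052	gene-033	gene-276	gene-170	gene-468	gene-469	gene-498	gene-486	gene-390	gene-137	gene-126	gene-250	gene-417	gene-278	gene-472	gene-072	gene-111	gene-048	gene-051
SET05	random synthetic set	gene-208	gene-236	gene-305	gene-477	gene-146	gene-111	gene-403	gene-374	gene-063	gene-157	gene-321	gene-383	gene-130	gene-120	gene-445	gene-168	gene-455	gene-485	gene-338	gene-231	gene-449	gene-419	gene-209	gene-372	gene-151
SET06	random synthetic set	gene-070	gene-369	gene-383	gene-487	gene-472	gene-307	gene-102	gene-390	gene-116	gene-467	gene-026	gene-492	gene-133	gene-277	gene-252	gene-117	gene-416	gene-091	gene-325	gene-044	gene-360	gene-463	gene-380	gene-452	gene-451
SET07	random synthetic set	gene-071	gene-317	gene-147	gene-348	gene-422	gene-209	gene-467	gene-204	gene-266	gene-186	gene-425	gene-394	gene-169	gene-350	gene-220	gene-325	gene-343	gene-213	gene-046	gene-126	gene-291	gene-459	gene-244	gene-379	gene-259
SET08	random synthetic set	gene-419	gene-357	gene-039	gene-428	gene-416	gene-077	gene-460	gene-020	gene-091	gene-319	gene-487	gene-490	gene-131	gene-267	gene-004	gene-453	gene-459	gene-486	gene-054	gene-099	gene-411	gene-164	gene-243	gene-199	gene-291
SET09	random synthetic set	gene-289	gene-249	gene-027	gene-366	gene-500	gene-298	gene-446	gene-176	gene-440	gene-028	gene-133	gene-216	gene-422	gene-159	gene-495	gene-312	gene-285	gene-023	gene-177	gene-134	gene-243	gene-487	gene-004	gene-137	gene-093
SET10	random synthetic set	gene-170	gene-183	gene-400	gene-495	gene-296	gene-059	gene-309	gene-273	gene-115	gene-214	gene-399	gene-257	gene-022	gene-431	gene-363	gene-033	gene-241	gene-166	gene-497	gene-383	gene-310	gene-256	gene-370	gene-165	gene-456
COUPLED_TARGETS	planted coupled targets	gene-021	gene-022	gene-023	gene-024	gene-025	gene-026	gene-027	gene-066	gene-004	gene-226	gene-406	gene-381	gene-481	gene-103	gene-095	gene-261	gene-317	gene-342	gene-213
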