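feature	direction	logfc
gene-001	+	2
gene-002	-	-2
gene-003	+	2
gene-004	-	-2
gene-005	+	2
gene-006	-	-2
gene-007	+	2
gene-008	-	-2
gene-009	+	2
gene-010	-	-2
gene-011	+	2
gene-012	-	-2
gene-013	+	2
gene-014	-	-2
gene-015	+	2
gene-016	-	-2
gene-017	+	2
gene-018	-	-2
gene-019	+	2
gene-020	-	-2
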