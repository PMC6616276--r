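PMID	PREDICATE	SUBJECT_CUI	SUBJECT_NAME	SUBJECT_SEMTYPE	OBJECT_CUI	OBJECT_NAME	OBJECT_SEMTYPE
10001	STIMULATES	C0028040	Nicotine	hops	C1000001	Brain-Derived Neurotrophic Factor	aapp
10002	STIMULATES	C0028040	Nicotine	hops	C1000001	Brain-Derived Neurotrophic Factor	aapp
10003	AFFECTS	C1000001	Brain-Derived Neurotrophic Factor	aapp	C0025260	Memory	menp
10004	AFFECTS	C1000001	Brain-Derived Neurotrophic Factor	aapp	C0023185	Learning	menp
10005	INHIBITS	C0039663	Tetrahydrocannabinol	orch	C1000001	Brain-Derived Neurotrophic Factor	aapp
10006	INHIBITS	C0028040	Nicotine	hops	C1000002	Neuropeptide Y	aapp
10007	AFFECTS	C1000002	Neuropeptide Y	aapp	C0025260	Memory	menp
10008	STIMULATES	C0028040	Nicotine	hops	C1000003	Vascular Endothelial Growth Factor	aapp
10009	AFFECTS	C1000003	Vascular Endothelial Growth Factor	aapp	C0025260	Memory	menp
10010	STIMULATES	C0039663	Tetrahydrocannabinol	orch	C1000004	Corticotropin-Releasing Hormone	aapp
10011	STIMULATES	C0028040	Nicotine	hops	C1000004	Corticotropin-Releasing Hormone	aapp
10012	AFFECTS	C1000004	Corticotropin-Releasing Hormone	aapp	C0023185	Learning	menp
10013	AFFECTS	C1000004	Corticotropin-Releasing Hormone	aapp	C0025260	Memory	menp
10014	STIMULATES	C0028040	Nicotine	hops	C1000005	Erythropoietin	aapp
10015	AFFECTS	C1000005	Erythropoietin	aapp	C0025260	Memory	menp
10016	AFFECTS	C0028040	Nicotine	hops	C0025260	Memory	menp
10017	AFFECTS	C0028040	Nicotine	hops	C0025260	Memory	menp
10018	AFFECTS	C0028040	Nicotine	hops	C0023185	Learning	menp
10019	AFFECTS	C0039663	Tetrahydrocannabinol	orch	C0025260	Memory	menp
10020	AFFECTS	C0039663	Tetrahydrocannabinol	orch	C0023185	Learning	menp
10021	INTERACTS_WITH	C0239059	Cigarette smoke	hops	C0028040	Nicotine	hops
10022	STIMULATES	C0239059	Cigarette smoke	hops	C1000003	Vascular Endothelial Growth Factor	aapp
10023	AFFECTS	C1000002	Neuropeptide Y	aapp	C0023185	Learning	menp
10024	INHIBITS	C0039663	Tetrahydrocannabinol	orch	C1000002	Neuropeptide Y	aapp
10025	STIMULATES	C0028040	Nicotine	hops	C1000006	Metabotropic Glutamate Receptor	aapp
10026	AFFECTS	C1000006	Metabotropic Glutamate Receptor	aapp	C0023185	Learning	menp
10027	AFFECTS	C1000006	Metabotropic Glutamate Receptor	aapp	C0025260	Memory	menp
10028	INHIBITS	C0039663	Tetrahydrocannabinol	orch	C1000006	Metabotropic Glutamate Receptor	aapp
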