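metabolite	rate	direction
Acetoacetate	0.012	uptake
Glutamine	0.500	release
Asparagine	0.0037	uptake
Ornithine	0.0031	uptake
Valine	0.0018	uptake
Serine	0.0016	uptake
Linoleate	0.0011	uptake
Threonine	0.0008	uptake
Isoleucine	0.0004	uptake
Methionine	0.0017	uptake
Tyrosine	0.0017	uptake
Arginine	0.0025	uptake
Histidine	0.0025	uptake
Cystine	0.0045	uptake
Lysine	0.011	uptake
Leucine	0.0145	uptake
Glutamate	0.232	uptake
Acetate	0.0013	uptake
Glycine	0.0053	uptake
Proline	0.0066	uptake
Alanine	0.0079	uptake
Glucose	0.19	uptake
CMR_O2	0.530	uptake
CMR_CO2	0.515	release
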