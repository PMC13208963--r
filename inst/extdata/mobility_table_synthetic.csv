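taxon,strain,mu_ek_m2_per_Vs,mu_dep_m4_per_V2s,source
Staphylococcus epidermidis,synthetic-A,4.0e-09,-4.1e-19,synthetic example
Staphylococcus epidermidis,synthetic-B,4.3e-09,-3.6e-19,synthetic example
Staphylococcus aureus,synthetic-MR,6.2e-09,-6.3e-19,synthetic example
Staphylococcus aureus,synthetic-MS,5.8e-09,-5.1e-19,synthetic example
Escherichia coli,synthetic-1,5.1e-09,-2.2e-19,synthetic example
Listeria monocytogenes,synthetic-1,3.2e-09,-2.9e-19,synthetic example
Salmonella enterica,synthetic-1,4.8e-09,-3.3e-19,synthetic example
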