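family_accession	clan_accession
PF01582	CL0173
PF13676	CL0173
PF00560	CL0022
PF13855	CL0022
PF12799	CL0022
PF13516	CL0022
PF13306	CL0022
PF00047	CL0011
PF07679	CL0011
PF13927	CL0011
PF07686	CL0011
PF00531	CL0041
PF00619	CL0041
PF02758	CL0041
PF01335	CL0041
PF05729	CL0023
PF00069	CL0016
PF07714	CL0016
PF00071	CL0023
PF08477	CL0023
PF08699	CL0023
PF00023	CL0465
PF12796	CL0465
PF00018	CL0010
PF00536	CL0003
PF00431	CL0164
PF00089	CL0124
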