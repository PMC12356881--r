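probe	chrom	pval
cg21545890	4	2.44e-7
cg09289469	4	4.83e-6
cg02730678	6	6.29e-7
cg14289643	8	3.93e-6
cg25129781	11	1.92e-10
cg08142096	11	3.59e-9
cg09213929	11	5.74e-10
cg10045354	11	8.18e-8
cg21645554	11	5.46e-7
cg25366390	12	2.23e-6
cg22163059	12	2.50e-6
cg22964621	14	2.97e-6
cg21924449	15	8.96e-7
cg00129232	17	5.58e-6
cg13840032	18	1.77e-6
cg22601191	20	2.15e-8
cg01379171	20	4.97e-6
cg22307297	20	4.47e-6
cg26561207	20	7.52e-6
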