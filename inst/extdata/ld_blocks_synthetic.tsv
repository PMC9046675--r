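variant	rs2228145	rs7518199	rs4537545	rs7529229	rs4129267	rs4845625	rs4845618	rs4845371	rs6667434	rs4553185
rs2228145	1.00	0.90	0.90	0.90	0.90	0.05	0.05	0.05	0.05	0.05
rs7518199	0.90	1.00	0.90	0.90	0.90	0.05	0.05	0.05	0.05	0.05
rs4537545	0.90	0.90	1.00	0.90	0.90	0.05	0.05	0.05	0.05	0.05
rs7529229	0.90	0.90	0.90	1.00	0.90	0.05	0.05	0.05	0.05	0.05
rs4129267	0.90	0.90	0.90	0.90	1.00	0.05	0.05	0.05	0.05	0.05
rs4845625	0.05	0.05	0.05	0.05	0.05	1.00	0.90	0.90	0.90	0.90
rs4845618	0.05	0.05	0.05	0.05	0.05	0.90	1.00	0.90	0.90	0.90
rs4845371	0.05	0.05	0.05	0.05	0.05	0.90	0.90	1.00	0.90	0.90
rs6667434	0.05	0.05	0.05	0.05	0.05	0.90	0.90	0.90	1.00	0.90
rs4553185	0.05	0.05	0.05	0.05	0.05	0.90	0.90	0.90	0.90	1.00
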