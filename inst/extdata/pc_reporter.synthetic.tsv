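# SYNTHETIC reporter measurements (fluorescence units at OD600 = 1),
# constructed to exercise the delta-FU / not-detected rules: positive
# promoters, a negative control with uninduced > induced, and a weak
# promoter whose replicate SD exceeds its delta-FU.
strain_label	fu_induced	fu_uninduced	sd	n
Bccel_5622	1840	210	145	3
Bccel_3806	960	185	88	3
Bccel_5179	2230	240	160	3
Bccel_5541	640	170	95	3
Bccel_5619	1110	205	120	3
Bccel_5627	770	190	101	3
sigI3_neg	230	260	40	3
weak_X	300	250	75	3
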