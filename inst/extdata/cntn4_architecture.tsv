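# CNTN4 ectodomain modular architecture: six IgC2 domains, each restrained by
# one disulfide bridge sheltering roughly half of the module, followed by four
# FnIII domains with no clamp.
#
# NOTE: the per-domain residue partitions below are SYNTHETIC placeholders.
# The published per-domain counts exist only in a figure image that is not
# machine-readable; these rows were chosen once so that every derived quantity
# is consistent with the printed population values (predicted stretched
# lengths: IgC2 10-18 nm, FnIII 29-33 nm at 0.38 nm per residue; ~1000
# residues overall; the bridge clamps about half of each IgC2 module).
# Columns: n_res = total residues; n_protected = residues inside the Cys-Cys
# bridge (extension-sheltered); linker_after = free residues to the next
# module; d_fold = folded N-to-C span (nm) subtracted from the stretched
# contour when predicting unfolding lengths.
name	dclass	n_res	n_protected	linker_after	d_fold
IgC2_1	IgC2	95	56	4	4.5
IgC2_2	IgC2	96	55	4	4.5
IgC2_3	IgC2	97	54	5	4.5
IgC2_4	IgC2	98	43	4	4.5
IgC2_5	IgC2	99	42	5	4.5
IgC2_6	IgC2	100	41	4	4.5
FnIII_1	FnIII	90	0	5	4.5
FnIII_2	FnIII	93	0	4	4.5
FnIII_3	FnIII	95	0	5	4.5
FnIII_4	FnIII	97	0	0	4.5
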