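# Template for a literature-derived profile (e.g. the thresholds used to
# assemble curated docking sets).  Fill in the numeric values from the
# source you are reproducing before loading; 'off' disables a condition.
name=Iridium (user template)
source=PDB
rscc_min=off
occupancy_min=off
rsr_good_max=0.1
rsr_max=0.3
owab_max=off
r_free_max=off
resolution_max=off
tolerance=1
site_cutoff=4.5
bond_cutoff=2.1
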