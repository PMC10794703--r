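# United-atom van der Waals radii (Angstrom) for heavy atoms; hydrogens are
# absorbed into the heavy-atom radii. Matches the package default vdw_radii().
provenance: "united-atom heavy-atom radii, Chothia-type values"
C: 1.9
N: 1.7
O: 1.4
S: 1.8
P: 1.8
H: 1.0
.default: 1.7
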