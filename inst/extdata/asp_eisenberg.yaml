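# Atomic solvation parameters, cal/(mol*A^2).
# Five-class set of the Eisenberg-McLachlan type: apolar carbon, neutral
# N/O, charged carboxylate oxygen, charged nitrogen, sulfur.
# Convention: sigma multiplies ACCESSIBLE area in a solvation free energy;
# the package scores burial as energy = -sigma * buried_area.
provenance: "Eisenberg-McLachlan five-class atomic solvation set (1986-type values)"
sigma:
  C: 16
  "N": -6
  "O": -6
  "O-": -24
  "N+": -50
  S: 21
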