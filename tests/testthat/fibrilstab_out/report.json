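{
  "config": {
    "seed": 2,
    "output_dir": "fibrilstab_out",
    "synthetic": {
      "gate_states": "broken",
      "n_layers": 3
    },
    "stability": {
      "stack_layers": 3,
      "n_points": 240,
      "reference": "isolated_chain"
    },
    "tracing": {
      "star": "/tmp/RtmphpeGEn/file89056e6d76c.star"
    },
    "compare": {
      "layers": 3,
      "fit_set": "all_shared"
    }
  },
  "timestamp": "2026-10-02 06:41:22 UTC",
  "helix": {
    "broken": {
      "twist": -1.3,
      "rise": 4.96,
      "crossover": 686.769230769231,
      "estimated_twist": -1.3,
      "estimated_rise": 4.96
    }
  },
  "stability": {
    "broken": {
      "chain_energy": -66.0302153518336,
      "n_residues": 83,
      "energy_per_residue": -0.795544763275103,
      "context": {
        "stack_layers": 3,
        "scored_layer": 1,
        "probe": 1.4,
        "n_points": 240,
        "reference": "isolated_chain",
        "asp_provenance": "Eisenberg-McLachlan five-class atomic solvation set (1986-type values)",
        "sign_convention": "energy = -sigma * buried_area; stabilizing burial is negative kcal/mol",
        "units": "kcal/mol"
      }
    }
  },
  "tracing": {
    "n_filaments": 20,
    "n_segments": 400,
    "counts": {
      "pure": 0,
      "mixed": 20,
      "unassigned": 0
    },
    "mixed_fraction": 1,
    "mean_coverage": 1,
    "lower_bound": false,
    "caveat": "Only labeled segments are informative: with incomplete coverage the mixed count is a lower bound, and filaments classified as pure cannot be ruled out to contain one type or both."
  }
}
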