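{
  "global": {
    "seed": 1,
    "temperature": 298
  },
  "steps": [
    {
      "type": "synth_study",
      "name": "study",
      "settings": {
        "n_ligands": 10,
        "dg_range": [-11.5, -7.2],
        "edge_noise_sd": 0.3,
        "exp_noise_sd": 0.43,
        "target_degree": 3
      }
    },
    {
      "type": "mock_nes",
      "name": "nes",
      "inputs": { "study": "study" },
      "settings": {
        "dissipation_sigma": 1.0,
        "n_transitions": 80,
        "n_replicas": 3
      }
    },
    {
      "type": "estimate_edges",
      "name": "edges",
      "inputs": { "works": "nes" },
      "settings": { "n_boot": 100 }
    },
    {
      "type": "solve_graph",
      "name": "graph",
      "inputs": { "map": "study", "edges": "edges" }
    },
    {
      "type": "offset_experiment",
      "name": "offset",
      "inputs": { "nodes": "graph", "experiment": "study" }
    },
    {
      "type": "metrics",
      "name": "metrics",
      "inputs": { "nodes": "offset", "experiment": "offset" },
      "settings": { "n_boot": 500, "n_samples": 500 }
    },
    {
      "type": "report",
      "name": "report"
    }
  ]
}
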