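{
  "description": "Full-scale stimulation-parameter study grid (cluster-scale): both sequence modes over the complete intensity/period grid with 11 replicate networks and the unscaled four-phase schedule.",
  "modes": ["rvs", "svs"],
  "l": 100,
  "K": [0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50],
  "T_s_ms": [64, 40, 29, 23, 19, 16, 14, 12, 11, 10, 9],
  "T_s_fine_scan_ms": {"from": 9, "to": 40, "by": 1, "K": 0.20},
  "replicates": 11,
  "duration_scale": 1.0,
  "schedule_ms": {"equilibration": 2000, "kindling": 60000, "cr_on": 128000, "cr_off": 128000},
  "usage": "spec <- sweep_spec(K = cfg$K, T_s = cfg$T_s_ms, modes = cfg$modes, l = cfg$l, replicates = cfg$replicates); run_sweep(spec, seed = 1, cache_dir = 'sweep-cache')"
}
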