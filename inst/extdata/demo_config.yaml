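# Demo pipeline configuration: synthesize a small hyperexcitable recording
# and run every analysis stage on it.
seed: 42
outdir: hdmea_demo
stages:
  synth: true
  spikes: true
  network: true
  lfp: true
  csd: true
synth:
  condition: hyper
  n_rows: 8
  n_cols: 8
  duration_s: 10
  sampling_rate_hz: 3000
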