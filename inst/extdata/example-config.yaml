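# Example run configuration for the adaptbci command line.
# `adaptbci generate --config example-config.yaml --out out/` writes a
# synthetic session; `adaptbci simulate --config ...` runs the Auto
# configuration on it (or on a `session:` file if one is given).
seed: 1
montage: default
mode: auto
derivations: [FCz-CPz, P1-P2, CP4-PO4]
classes: [Feet, Hand, Word, Math]
nInitTpc: 7
nUpdateTpc: 7
generator:
  classes: [Feet, Hand, Word, Math, Nav]
  runs: 8
  trialsPerClassPerRun: 5
  artifactRate: 0.05
  seed: 1
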