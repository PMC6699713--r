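# Paired specialist/generalist experiment on the gut fermentation pathway.
# Unset options take the package defaults; `load_config()` echoes the full
# effective configuration.
preset: gut_11
mode: experiment
seed: 1
reps: 200
arms:
  - specialist_eco
  - generalist_eco
  - generalist_evo
a: 1
mu: 0.01
t_end: 20000
out: gut_run
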