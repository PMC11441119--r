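# Sidak FWER: varying bias-effect magnitude, N = 32, m = 2
procedure: sidak
alpha: 0.05
r: 100000
seed: 20240930
rps:
  - {name: CR}
  - {name: BSD, b: 3}
  - {name: MP, b: 3}
  - {name: PBR, block_size: 4}
  - {name: RAR}
  - {name: EBC, p: 0.67}
  - {name: CHEN, p: 0.67, b: 2}
cases:
  - {"N": 32, m: 2, nu: 0.01, effect_sizes: 1.024}
  - {"N": 32, m: 2, nu: 0.05, effect_sizes: 1.024}
  - {"N": 32, m: 2, nu: 0.1, effect_sizes: 1.024}
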