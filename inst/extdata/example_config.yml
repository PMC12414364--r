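# Example comparison: conventional vs stepped-down vs intensified milk plan.
scenarios:
  - label: conventional_6L
    initial_bw: 40
    temperature: 20
    weaning_age: 56
    horizon: 84
    liquid:
      kind: whole_milk
      dm_fraction: 0.125
      me_density: 5.37
      cost_per_litre: 0.45
    starter:
      cp: 0.22
      ndf: 0.15
      fat: 0.04
      ash: 0.07
      dm: 0.90
      form: texturized
      cost_per_kg: 0.50
    allowance: 6
  - label: step_down_8L
    initial_bw: 40
    temperature: 20
    weaning_age: 56
    horizon: 84
    liquid:
      kind: whole_milk
      dm_fraction: 0.125
      me_density: 5.37
      cost_per_litre: 0.45
    starter:
      cp: 0.22
      ndf: 0.15
      fat: 0.04
      ash: 0.07
      dm: 0.90
      form: texturized
      cost_per_kg: 0.50
    allowance:
      - day: 1
        litres: 8
      - day: 43
        litres: 4
      - day: 50
        litres: 2
  - label: intensified_10L
    initial_bw: 40
    temperature: 20
    weaning_age: 56
    horizon: 84
    liquid:
      kind: milk_replacer
      dm_fraction: 0.96
      me_density: 4.60
      cost_per_litre: 0.40
      mixing_rate_g_l: 135
    starter:
      cp: 0.22
      ndf: 0.15
      fat: 0.04
      ash: 0.07
      dm: 0.90
      form: texturized
      cost_per_kg: 0.50
    allowance: 10
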