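rating_scale_max: 100.0
zero_substitute: 0.01
topics:
- id: farm
  name: farm
  trr: 30.0
  factors:
  - id: farm_01
    label: Placeholder statement 1 for topic 'farm'
  - id: farm_02
    label: Placeholder statement 2 for topic 'farm'
  - id: farm_03
    label: Placeholder statement 3 for topic 'farm'
  - id: farm_04
    label: Placeholder statement 4 for topic 'farm'
  - id: farm_05
    label: Placeholder statement 5 for topic 'farm'
- id: animals
  name: animals
  trr: 30.0
  factors:
  - id: animals_01
    label: Placeholder statement 1 for topic 'animals'
  - id: animals_02
    label: Placeholder statement 2 for topic 'animals'
  - id: animals_03
    label: Placeholder statement 3 for topic 'animals'
  - id: animals_04
    label: Placeholder statement 4 for topic 'animals'
  - id: animals_05
    label: Placeholder statement 5 for topic 'animals'
- id: treatment
  name: treatment
  trr: 20.0
  factors:
  - id: treatment_01
    label: Placeholder statement 1 for topic 'treatment'
  - id: treatment_02
    label: Placeholder statement 2 for topic 'treatment'
  - id: treatment_03
    label: Placeholder statement 3 for topic 'treatment'
  - id: treatment_04
    label: Placeholder statement 4 for topic 'treatment'
- id: nutrition
  name: nutrition
  trr: 20.0
  factors:
  - id: nutrition_01
    label: Placeholder statement 1 for topic 'nutrition'
  - id: nutrition_02
    label: Placeholder statement 2 for topic 'nutrition'
  - id: nutrition_03
    label: Placeholder statement 3 for topic 'nutrition'
  - id: nutrition_04
    label: Placeholder statement 4 for topic 'nutrition'
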