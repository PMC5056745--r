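n_stations: 60.0
survey_start: '2013-03-01'
survey_end: '2014-10-15'
deployment_mean_days: 40.0
deployment_sd_days: 5.0
centroid:
- 32.9
- 104.1
coord_jitter: 0.5
tz_offset: 8.0
prob_slow_camera: 0.4
dup_photo_prob: 0.5
seed: 1.0
species:
- species: masked_palm_civet
  psi: 0.5
  daily_rate: 0.08
  archetype:
    means:
    - 22.0
    - 4.0
    kappas:
    - 3.0
    - 3.0
    weights:
    - 0.55
    - 0.45
  winter_archetype: ~
  monthly:
  - 0.0
  - 0.0
  - 0.6
  - 0.8
  - 1.0
  - 1.4
  - 1.6
  - 1.6
  - 1.4
  - 0.8
  - 0.5
  - 0.0
- species: hog_badger
  psi: 0.6
  daily_rate: 0.112
  archetype:
    means:
    - 22.0
    - 4.0
    kappas:
    - 3.0
    - 3.0
    weights:
    - 0.55
    - 0.45
  winter_archetype: ~
  monthly:
  - 0.0
  - 0.0
  - 0.6
  - 0.8
  - 1.0
  - 1.4
  - 1.6
  - 1.6
  - 1.4
  - 0.8
  - 0.5
  - 0.0
- species: yellow_throated_marten
  psi: 0.45
  daily_rate: 0.064
  archetype:
    means:
    - 9.0
    - 15.0
    kappas:
    - 4.0
    - 4.0
    weights:
    - 0.5
    - 0.5
  winter_archetype: ~
  monthly:
  - 1.6
  - 1.2
  - 0.8
  - 0.8
  - 0.8
  - 0.8
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.2
  - 1.8
- species: siberian_weasel
  psi: 0.6
  daily_rate: 0.12
  archetype:
    means: 12.0
    kappas: 0.2
    weights: 1.0
  winter_archetype:
    means:
    - 22.0
    - 4.0
    kappas:
    - 3.0
    - 3.0
    weights:
    - 0.55
    - 0.45
  monthly:
  - 1.4
  - 1.2
  - 1.0
  - 0.7
  - 0.7
  - 0.8
  - 1.3
  - 1.4
  - 1.3
  - 0.8
  - 0.9
  - 1.5
pairs:
- species_a: masked_palm_civet
  species_b: hog_badger
  gamma: 0.6
- species_a: yellow_throated_marten
  species_b: siberian_weasel
  gamma: 1.4
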