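seed: 42
stages:
- synth
- ecog
- histology
- stats
ecog_params:
  fs_hz: 1000.0
  duration_s: 300.0
  day1_duration_s: 120.0
  rms_uv: 50.0
  alpha: 1.0
  amplitude_multiple: 5.0
  carrier_hz: 80.0
  event_duration_s: 3.0
  k_sd: 3.0
histology_params:
  n_sections: 6.0
  eb_threshold: 120.0
  eb_blob_blue: 180.0
  loss_jitter_sd: 0.05
  eb_fraction_jitter_sd: 0.03
groups:
- name: Sham
  n_animals: 8.0
  n_events: 0.0
  lesion_loss: 0.0
  eb_fraction: 0.01
- name: RB
  n_animals: 9.0
  n_events: 8.0
  lesion_loss: 0.371
  eb_fraction: 0.25
- name: RB-SPG-15min
  n_animals: 8.0
  n_events: 2.0
  lesion_loss: 0.206
  eb_fraction: 0.1
- name: RB-SPG-24h
  n_animals: 6.0
  n_events: 2.0
  lesion_loss: 0.179
  eb_fraction: 0.1
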