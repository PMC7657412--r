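{
  "_comment": "Optical model presets: B = blood volume fraction, S = oxygen saturation, mua0 = baseline absorption (mm^-1), scattering power law mus' = scat_prefactor * (lambda/500)^(-scat_power) (mm^-1).",
  "blood_patient1": {"B": 1.0, "S": 0.99, "mua0": 0.001, "scat_prefactor": 2.2, "scat_power": 0.66},
  "blood_patient2": {"B": 1.0, "S": 0.99, "mua0": 0.01, "scat_prefactor": 2.2, "scat_power": 0.66},
  "blood_patient3": {"B": 1.0, "S": 0.98, "mua0": 0.01, "scat_prefactor": 2.2, "scat_power": 0.66},
  "cortex_patient1": {"B": 0.5, "S": 0.9, "mua0": 0.001, "scat_prefactor": 2.42, "scat_power": 1.661},
  "cortex_patient2": {"B": 0.5, "S": 0.9, "mua0": 0.01, "scat_prefactor": 2.42, "scat_power": 1.661},
  "cortex_patient3": {"B": 0.5, "S": 0.9, "mua0": 0.01, "scat_prefactor": 2.42, "scat_power": 1.661},
  "blood_default": {"alias": "blood_patient1"},
  "cortex_default": {"alias": "cortex_patient1"}
}
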