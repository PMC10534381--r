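{
  "catalog_version": "1.0",
  "description": "Physical and electrical single-shell properties of the separated species: circulating tumor cells (CTC), white blood cells (WBC) and platelets (PLT).",
  "species": [
    {
      "name": "CTC",
      "diameter_um": 15,
      "membrane_thickness_nm": 7,
      "cytoplasm_conductivity_S_m": 1,
      "membrane_conductivity_S_m": 9e-7,
      "cytoplasm_rel_permittivity": 50,
      "membrane_rel_permittivity": 12.5
    },
    {
      "name": "WBC",
      "diameter_um": 12,
      "membrane_thickness_nm": 7,
      "cytoplasm_conductivity_S_m": 0.18,
      "membrane_conductivity_S_m": 9e-6,
      "cytoplasm_rel_permittivity": 80,
      "membrane_rel_permittivity": 10
    },
    {
      "name": "PLT",
      "diameter_um": 1.8,
      "membrane_thickness_nm": 8,
      "cytoplasm_conductivity_S_m": 0.25,
      "membrane_conductivity_S_m": 1e-6,
      "cytoplasm_rel_permittivity": 50,
      "membrane_rel_permittivity": 6
    }
  ]
}
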