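{
  "entity_types": ["Syndrome", "SubSyndrome", "Symptom", "PathogenesisFactor", "Prescription", "TreatmentMethod", "Other"],
  "relations": [
    {
      "name": "Manifest",
      "domain": "any",
      "range": "Symptom",
      "transitive": false,
      "symmetric": false
    },
    {
      "name": "Contain",
      "domain": "any",
      "range": "any",
      "transitive": true,
      "symmetric": false
    },
    {
      "name": "CorrespondTo",
      "domain": "Symptom",
      "range": "PathogenesisFactor",
      "transitive": false,
      "symmetric": false
    },
    {
      "name": "Treat",
      "domain": "Prescription",
      "range": "any",
      "transitive": false,
      "symmetric": false,
      "exclusive_with": "ContraindicationIs"
    },
    {
      "name": "DifferentialDiagnosisIs",
      "domain": "any",
      "range": "any",
      "transitive": false,
      "symmetric": true
    },
    {
      "name": "ContraindicationIs",
      "domain": "Prescription",
      "range": "any",
      "transitive": false,
      "symmetric": false,
      "exclusive_with": "Treat"
    },
    {
      "name": "TreatmentMethodIs",
      "domain": "any",
      "range": "TreatmentMethod",
      "transitive": false,
      "symmetric": false
    }
  ],
  "entity_type_map": {
    "TaiYang": "Syndrome",
    "YangMing": "Syndrome",
    "JueYin": "Syndrome",
    "WindCold": "PathogenesisFactor",
    "ExteriorDeficiency": "PathogenesisFactor",
    "InteriorHeat": "PathogenesisFactor",
    "Dryness": "PathogenesisFactor",
    "ColdLimit": "PathogenesisFactor",
    "UpperHeat": "PathogenesisFactor",
    "fever": "Symptom",
    "aversion to wind": "Symptom",
    "thirst": "Symptom",
    "constipation": "Symptom",
    "cold limbs": "Symptom",
    "spontaneous sweating": "Symptom",
    "shivering": "Symptom",
    "Cassia Twig Decoction": "Prescription",
    "White Tiger Decoction": "Prescription",
    "Fructus Mume Pill": "Prescription",
    "Cassia Twig Decoction Syndrome": "SubSyndrome"
  }
}
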