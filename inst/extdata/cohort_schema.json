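[
  {
    "name": "patient_id",
    "type": "id",
    "unit": "",
    "levels": "",
    "mandatory": false,
    "description": "Opaque patient identifier; all lesions of a patient share it."
  },
  {
    "name": "lesion_id",
    "type": "id",
    "unit": "",
    "levels": "",
    "mandatory": false,
    "description": "Opaque per-target identifier, unique within patient."
  },
  {
    "name": "age_years",
    "type": "numeric",
    "unit": "years",
    "levels": "",
    "mandatory": false,
    "description": "Age at treatment."
  },
  {
    "name": "sex",
    "type": "category",
    "unit": "",
    "levels": "M/F",
    "mandatory": false,
    "description": "Sex."
  },
  {
    "name": "kps",
    "type": "grid",
    "unit": "points",
    "levels": "40/50/60/70/80/90/100",
    "mandatory": false,
    "description": "Karnofsky Performance Status before radiosurgery (40-100, steps of 10)."
  },
  {
    "name": "volume_cm3",
    "type": "numeric",
    "unit": "cm3",
    "levels": "",
    "mandatory": false,
    "description": "Pre-treatment contrast-enhancing target volume."
  },
  {
    "name": "anatomic_loc",
    "type": "category",
    "unit": "",
    "levels": "1/2/3/4/5/6",
    "mandatory": false,
    "description": "Anatomic localization: 1 frontal, 2 parietal, 3 occipital, 4 temporal, 5 cerebellar, 6 other/deep midline."
  },
  {
    "name": "tumor_loc",
    "type": "category",
    "unit": "",
    "levels": "1/2/3",
    "mandatory": false,
    "description": "Tumor localization: 1 cortical/sub-cortical, 2 deep-seated/midline, 3 multifocal."
  },
  {
    "name": "dose_gy",
    "type": "numeric",
    "unit": "Gy",
    "levels": "",
    "mandatory": false,
    "description": "Prescription dose at the covering isodose surface."
  },
  {
    "name": "isodose_pct",
    "type": "numeric",
    "unit": "%",
    "levels": "",
    "mandatory": false,
    "description": "Prescription isodose line as percentage of maximum dose."
  },
  {
    "name": "max_gy",
    "type": "numeric",
    "unit": "Gy",
    "levels": "",
    "mandatory": false,
    "description": "Maximum dose in the target; approximately dose_gy / (isodose_pct/100)."
  },
  {
    "name": "coverage",
    "type": "numeric",
    "unit": "fraction",
    "levels": "",
    "mandatory": false,
    "description": "Fraction of the target covered by the prescription isodose."
  },
  {
    "name": "mgmt",
    "type": "category",
    "unit": "",
    "levels": "methyl/unmethyl",
    "mandatory": false,
    "description": "MGMT promoter methylation status."
  },
  {
    "name": "egfr",
    "type": "category",
    "unit": "",
    "levels": "ampl/unampl/mut/unmut",
    "mandatory": false,
    "description": "EGFR status as recorded (amplification and mutation vocabularies mixed in source coding)."
  },
  {
    "name": "pten",
    "type": "category",
    "unit": "",
    "levels": "mut/umut",
    "mandatory": false,
    "description": "PTEN status."
  },
  {
    "name": "tert",
    "type": "category",
    "unit": "",
    "levels": "mut/unmut",
    "mandatory": false,
    "description": "TERT promoter status."
  },
  {
    "name": "chr7p10q",
    "type": "category",
    "unit": "",
    "levels": "yes/no",
    "mandatory": false,
    "description": "Combined chromosome 7 gain / 10 loss signature."
  },
  {
    "name": "time_months",
    "type": "numeric",
    "unit": "months",
    "levels": "",
    "mandatory": true,
    "description": "Follow-up: months from radiosurgery to local failure or last imaging."
  },
  {
    "name": "event",
    "type": "event",
    "unit": "",
    "levels": "",
    "mandatory": true,
    "description": "1 = documented local failure, 0 = censored at last imaging."
  }
]
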