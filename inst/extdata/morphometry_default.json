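{
  "schema_version": "1.0",
  "provenance": "Calibrated 19-level neonatal cerebrovascular morphometry. Level geometry/counts fitted so that, at the 25-week reference (brain weight 130 g), total resistance at systemic hematocrit 15/45/60% approximates the hematocrit-dependent assembly targets; capillary-level counts anchored to the two-phase capillary resistances.",
  "reference_brain_weight_g": 130,
  "scaling_exponents": {
    "count": 1,
    "length": 0,
    "diameter": 0
  },
  "brain_weight_table": {
    "ga_weeks": [22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36],
    "weight_g": [81.3, 95.1, 111.2, 130, 152, 177.7, 207.8, 242.9, 283.4, 315, 345, 372, 395, 412, 425]
  },
  "birth_weight_allometry": {
    "coef": 0.467887322896037,
    "exponent": 0.85
  },
  "levels": [
    {
      "j": 1,
      "name": "large cerebral arteries",
      "count": 3.94919606318424,
      "diameter_um": 1300,
      "length_um": 30000,
      "compartment": "arterial"
    },
    {
      "j": 2,
      "name": "main arterial branches",
      "count": 15.2335297940033,
      "diameter_um": 800,
      "length_um": 20000,
      "compartment": "arterial"
    },
    {
      "j": 3,
      "name": "small arteries",
      "count": 49.6073812691274,
      "diameter_um": 500,
      "length_um": 12000,
      "compartment": "arterial"
    },
    {
      "j": 4,
      "name": "pial arteries",
      "count": 153.358513363256,
      "diameter_um": 300,
      "length_um": 6000,
      "compartment": "arterial"
    },
    {
      "j": 5,
      "name": "small pial arteries",
      "count": 1024.72858146291,
      "diameter_um": 150,
      "length_um": 3500,
      "compartment": "arterial"
    },
    {
      "j": 6,
      "name": "penetrating arterioles",
      "count": 4911.51886320464,
      "diameter_um": 80,
      "length_um": 2000,
      "compartment": "arterial"
    },
    {
      "j": 7,
      "name": "arterioles",
      "count": 10877.8822109906,
      "diameter_um": 50,
      "length_um": 1000,
      "compartment": "arterial"
    },
    {
      "j": 8,
      "name": "small arterioles",
      "count": 75910.7257248703,
      "diameter_um": 25,
      "length_um": 400,
      "compartment": "arterial"
    },
    {
      "j": 9,
      "name": "precapillary arterioles",
      "count": 8192552.58072176,
      "diameter_um": 13.2793448155568,
      "length_um": 3284.06614794658,
      "compartment": "precapillary"
    },
    {
      "j": 10,
      "name": "capillaries",
      "compartment": "capillary"
    },
    {
      "j": 11,
      "name": "postcapillary venules",
      "count": 649105.480925706,
      "diameter_um": 18,
      "length_um": 300,
      "compartment": "venous"
    },
    {
      "j": 12,
      "name": "small venules",
      "count": 27961.1285490453,
      "diameter_um": 40,
      "length_um": 600,
      "compartment": "venous"
    },
    {
      "j": 13,
      "name": "venules",
      "count": 5512.54029669876,
      "diameter_um": 80,
      "length_um": 1200,
      "compartment": "venous"
    },
    {
      "j": 14,
      "name": "small veins",
      "count": 1382.35878739696,
      "diameter_um": 160,
      "length_um": 2500,
      "compartment": "venous"
    },
    {
      "j": 15,
      "name": "veins",
      "count": 183.197047025496,
      "diameter_um": 350,
      "length_um": 5000,
      "compartment": "venous"
    },
    {
      "j": 16,
      "name": "large veins",
      "count": 21.8000175284959,
      "diameter_um": 700,
      "length_um": 8000,
      "compartment": "venous"
    },
    {
      "j": 17,
      "name": "deep veins",
      "count": 9.65569546633015,
      "diameter_um": 1000,
      "length_um": 12000,
      "compartment": "venous"
    },
    {
      "j": 18,
      "name": "sinuses",
      "count": 7.16636229378549,
      "diameter_um": 1300,
      "length_um": 20000,
      "compartment": "venous"
    },
    {
      "j": 19,
      "name": "outflow veins",
      "count": 4.7343745152427,
      "diameter_um": 1600,
      "length_um": 25000,
      "compartment": "venous"
    }
  ],
  "gm": {
    "gm_diameter_um": 6.57731473059172,
    "gm_length_um": 368.997802777501,
    "ngm_diameter_um": 5.6,
    "ngm_length_um": 600,
    "gm_count": 630731.831458533,
    "ngm_count": 20569181.7845153,
    "involution_onset_wk": 25,
    "involution_complete_wk": 32
  },
  "rheology": {
    "mu_plasma_Pa_s": 0.001,
    "wall_offset_um": 1.1
  },
  "two_phase": {
    "mu_rbc_Pa_s": 0.1
  }
}
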