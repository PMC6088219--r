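{
  "ghq12": ["ghq_1", "ghq_2", "ghq_3", "ghq_4", "ghq_5", "ghq_6",
            "ghq_7", "ghq_8", "ghq_9", "ghq_10", "ghq_11", "ghq_12"],
  "hads_anxiety": ["hads_1", "hads_3", "hads_5", "hads_7", "hads_9",
                   "hads_11", "hads_13"],
  "hads_depression": ["hads_2", "hads_4", "hads_6", "hads_8", "hads_10",
                      "hads_12", "hads_14"],
  "sle": ["sle_1", "sle_2", "sle_3", "sle_4", "sle_5", "sle_6", "sle_7",
          "sle_8", "sle_9", "sle_10", "sle_11", "sle_12", "sle_13",
          "sle_14", "sle_15", "sle_16", "sle_17", "sle_18", "sle_19",
          "sle_20", "sle_21", "sle_22", "sle_23", "sle_24", "sle_25",
          "sle_26", "sle_27", "sle_28", "sle_29", "sle_30", "sle_31",
          "sle_32", "sle_33", "sle_34", "sle_35", "sle_36", "sle_37",
          "sle_38", "sle_39", "sle_40", "sle_41", "sle_42", "sle_43",
          "sle_44", "sle_45", "sle_46"],
  "eri_effort": ["eri_e1", "eri_e2", "eri_e3", "eri_e4", "eri_e5",
                 "eri_e6"],
  "eri_reward": ["eri_r1", "eri_r2", "eri_r3", "eri_r4", "eri_r5",
                 "eri_r6", "eri_r7", "eri_r8", "eri_r9", "eri_r10",
                 "eri_r11"],
  "ipaq": ["ipaq_vigorous_met", "ipaq_moderate_met", "ipaq_walksit_met"],
  "covariates": {
    "age": "age",
    "sex_female": "sex_female",
    "married": "married",
    "education": "education",
    "household_size": "household_size",
    "shift_work": "shift_work",
    "sleep_hours": "sleep_hours",
    "smoker": "smoker",
    "bmi": "bmi"
  }
}
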