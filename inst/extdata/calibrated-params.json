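{
  "U_L": 9.67885617164501,
  "U_R": 24,
  "V0_LV": -5.14236020590406,
  "V0_RV": 16.384044566543,
  "ERD": 0.025,
  "R_sa": 2.4,
  "R_ua": 0.8,
  "R_uv": 2.9,
  "R_la": 0.55,
  "R_va": 0.35,
  "R_lv": 0.45,
  "C_um": 0.05,
  "C_lm": 0.1,
  "C_arch_d": 1.8,
  "C_car_d": 0.5,
  "C_ab_d": 2.5,
  "C_il_d": 1,
  "C_sv": 30,
  "R_pa": 0.05,
  "R_pm": 0.04,
  "C_pa": 3,
  "C_pm": 10,
  "C_pv": 35,
  "R_sys_scale": 1.2659753591311,
  "R_pul_scale": 1.62863735873292,
  "C_per_scale": 1.06232405100663,
  "C_art_scale": 15,
  "L_art_scale": 0.03,
  "edge_damping": 0.4,
  "damping_ref": 2,
  "carotid_parallel": 4,
  "iliac_parallel": 2.5,
  "G_leak_tv": 1.33243171753472,
  "P_art0": 85,
  "P_um0": 80,
  "P_sv0": 1.84940722513905,
  "P_pa0": 15,
  "P_pm0": 10,
  "P_pv0": 9.09880432998559,
  "bcg_scale": 0.408821665705135,
  "init_states": {
    "idealized_male": {
      "lv": 155.291968294892,
      "asc_aorta": 33.1416316948915,
      "aortic_arch": 189.732366650129,
      "carotid": 51.2019911525373,
      "thoracic_aorta": 56.8609638896443,
      "abdominal_aorta": 257.822869834494,
      "iliac": 87.9461342330601,
      "upper_micro": 3.69026887175859,
      "lower_micro": 5.907665901492,
      "sys_veins": 118.622217432537,
      "rv": 166.871097021765,
      "pulm_artery": 47.162114970319,
      "pulm_micro": 130.500257323243,
      "pulm_veins": 244.736187717339,
      "q_arch": 4.66269924265791,
      "q_carotid": 3.20031584235129,
      "q_thoracic": 29.0776363615838,
      "q_abdominal": 36.7753065263754,
      "q_iliac": 20.6054796119787
    },
    "HR": {
      "lv": 152.744386400592,
      "asc_aorta": 33.5589989477447,
      "aortic_arch": 192.610631862474,
      "carotid": 51.9911385980377,
      "thoracic_aorta": 57.5655506498767,
      "abdominal_aorta": 261.58274801851,
      "iliac": 89.2468068236051,
      "upper_micro": 3.74845506188696,
      "lower_micro": 5.99084543968834,
      "sys_veins": 115.432336452272,
      "rv": 162.492069332025,
      "pulm_artery": 48.0948440340169,
      "pulm_micro": 131.994260604248,
      "pulm_veins": 242.434662763118,
      "q_arch": 4.78438145884413,
      "q_carotid": 3.09846862277203,
      "q_thoracic": 30.064268324075,
      "q_abdominal": 37.9152091676353,
      "q_iliac": 21.1212951190992
    },
    "ELS": {
      "lv": 148.745460284133,
      "asc_aorta": 33.6257677747189,
      "aortic_arch": 193.072677830981,
      "carotid": 52.0851908920393,
      "thoracic_aorta": 57.6902911721858,
      "abdominal_aorta": 262.357780368068,
      "iliac": 89.5274055243273,
      "upper_micro": 3.75721703488204,
      "lower_micro": 6.01550897534943,
      "sys_veins": 120.896499009968,
      "rv": 169.774277417814,
      "pulm_artery": 46.8900925411868,
      "pulm_micro": 129.105803536242,
      "pulm_veins": 235.94376262621,
      "q_arch": 4.74395402880548,
      "q_carotid": 3.27379670422682,
      "q_thoracic": 29.5628763259941,
      "q_abdominal": 37.3988625847571,
      "q_iliac": 20.9659228379145
    },
    "ELD": {
      "lv": 142.915001514263,
      "asc_aorta": 31.2411479953688,
      "aortic_arch": 176.620259302265,
      "carotid": 47.7243742181677,
      "thoracic_aorta": 53.6084299582508,
      "abdominal_aorta": 240.063621602459,
      "iliac": 81.7562759042312,
      "upper_micro": 3.42664205321721,
      "lower_micro": 5.48517961277288,
      "sys_veins": 109.452694110522,
      "rv": 155.148470960762,
      "pulm_artery": 47.7331017623888,
      "pulm_micro": 134.288258440597,
      "pulm_veins": 274.530255902931,
      "q_arch": 4.33089090250586,
      "q_carotid": 2.97469487468442,
      "q_thoracic": 27.0058339639732,
      "q_abdominal": 34.1562181386281,
      "q_iliac": 19.1393065118631
    },
    "ERS": {
      "lv": 156.808434192249,
      "asc_aorta": 33.3454649801783,
      "aortic_arch": 191.13838801417,
      "carotid": 51.5735782696947,
      "thoracic_aorta": 57.2085040138235,
      "abdominal_aorta": 259.706979823999,
      "iliac": 88.6004743913189,
      "upper_micro": 3.71688077311597,
      "lower_micro": 5.94633459784488,
      "sys_veins": 114.219338667537,
      "rv": 160.930419309713,
      "pulm_artery": 47.5741941127994,
      "pulm_micro": 131.677816710038,
      "pulm_veins": 247.040927131631,
      "q_arch": 4.70876296517388,
      "q_carotid": 3.23212743894659,
      "q_thoracic": 29.3646633668882,
      "q_abdominal": 37.1384264082096,
      "q_iliac": 20.8090603354362
    },
    "arterial_diameter": {
      "lv": 157.376512759382,
      "asc_aorta": 27.2233242129985,
      "aortic_arch": 185.838903076013,
      "carotid": 50.165622362992,
      "thoracic_aorta": 45.7135652018717,
      "abdominal_aorta": 247.470141573697,
      "iliac": 85.9647288891911,
      "upper_micro": 3.72553001866291,
      "lower_micro": 5.83623904851134,
      "sys_veins": 116.742708939907,
      "rv": 164.424365877384,
      "pulm_artery": 47.0570687237312,
      "pulm_micro": 130.491220508464,
      "pulm_veins": 247.410132598366,
      "q_arch": 4.28542633552541,
      "q_carotid": 2.27572199763333,
      "q_thoracic": 32.7387934880603,
      "q_abdominal": 39.3301648573909,
      "q_iliac": 20.9261263458823
    },
    "arterial_length": {
      "lv": 155.36449965144,
      "asc_aorta": 29.718714154675,
      "aortic_arch": 185.863255223502,
      "carotid": 50.2688571982492,
      "thoracic_aorta": 51.0330827080394,
      "abdominal_aorta": 253.110645350789,
      "iliac": 87.6062500045371,
      "upper_micro": 3.67585964479832,
      "lower_micro": 5.90557349243594,
      "sys_veins": 118.875920556874,
      "rv": 167.215528216312,
      "pulm_artery": 47.2132233069556,
      "pulm_micro": 130.629995941738,
      "pulm_veins": 244.867765606752,
      "q_arch": 4.22638129994158,
      "q_carotid": 3.32496179056042,
      "q_thoracic": 28.3582568099847,
      "q_abdominal": 35.4003061601652,
      "q_iliac": 20.1479554716839
    },
    "idealized_female": {
      "lv": 137.619757278988,
      "asc_aorta": 23.7867796034302,
      "aortic_arch": 176.859863148278,
      "carotid": 47.905954620943,
      "thoracic_aorta": 39.9989555404128,
      "abdominal_aorta": 236.406235757512,
      "iliac": 83.1644506836321,
      "upper_micro": 3.59300441855188,
      "lower_micro": 5.64668556542206,
      "sys_veins": 103.303146778112,
      "rv": 146.690373713111,
      "pulm_artery": 48.5581410652629,
      "pulm_micro": 135.092133913954,
      "pulm_veins": 266.586763242291,
      "q_arch": 3.76074506882774,
      "q_carotid": 2.11297752116053,
      "q_thoracic": 31.3059250415784,
      "q_abdominal": 37.1413793781519,
      "q_iliac": 20.0303456407191
    }
  }
}
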