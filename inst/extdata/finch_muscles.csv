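species,muscle,mass_g,fiber_length_mm,pathway
G_magnirostris,MDM,0.0522,3.99,none
G_magnirostris,MAMER,0.1813,2.31,indirect_jugal
G_magnirostris,MAMEV,0.0451,2.01,indirect_jugal
G_magnirostris,MAMEP,0.0595,2.02,indirect_jugal
G_magnirostris,MAMOQ,0.0084,2.58,indirect_jugal
G_magnirostris,MPsTSl,0.0137,1.36,indirect_jugal
G_magnirostris,MPsTSm,0.0624,1.39,indirect_jugal
G_magnirostris,MPsTP,0.0447,4.18,indirect_jugal
G_magnirostris,MPtVl,0.0752,2.58,direct_palatine
G_magnirostris,MPtVm,0.0758,2.56,direct_palatine
G_magnirostris,MPtDl,0.0568,2.56,direct_palatine
G_magnirostris,MPtDm,0.022,2.63,direct_palatine
G_magnirostris,MRPal,0.0104,2.61,direct_palatine
G_magnirostris,MPPtQ,0.0085,2.65,none
G_conirostris,MDM,0.0455,4.12,none
G_conirostris,MAMER,0.0389,2.55,indirect_jugal
G_conirostris,MAMEV,0.0178,2.93,indirect_jugal
G_conirostris,MAMEP,0.0262,2.37,indirect_jugal
G_conirostris,MAMOQ,0.0035,2.21,indirect_jugal
G_conirostris,MPsTSl,0.0033,1.81,indirect_jugal
G_conirostris,MPsTSm,0.0157,2.62,indirect_jugal
G_conirostris,MPsTP,0.0269,4.52,indirect_jugal
G_conirostris,MPtVl,0.0079,3.1,direct_palatine
G_conirostris,MPtVm,0.0253,3.2,direct_palatine
G_conirostris,MPtDl,0.024,3.42,direct_palatine
G_conirostris,MPtDm,0.0093,2.65,direct_palatine
G_conirostris,MRPal,0.0044,2.73,direct_palatine
G_conirostris,MPPtQ,0.0086,2.63,none
G_difficilis,MDM,0.005,2.91,none
G_difficilis,MAMER,0.0102,1.67,indirect_jugal
G_difficilis,MAMEV,0.0025,2.01,indirect_jugal
G_difficilis,MAMEP,0.0044,1.72,indirect_jugal
G_difficilis,MAMOQ,2e-04,1.64,indirect_jugal
G_difficilis,MPsTSl,6e-04,1.53,indirect_jugal
G_difficilis,MPsTSm,0.0012,2.15,indirect_jugal
G_difficilis,MPsTP,0.0064,2.76,indirect_jugal
G_difficilis,MPtVl,0.002,2.36,direct_palatine
G_difficilis,MPtVm,0.0055,4.32,direct_palatine
G_difficilis,MPtDl,0.0071,2.54,direct_palatine
G_difficilis,MPtDm,0.003,2.21,direct_palatine
G_difficilis,MRPal,0.0014,1.98,direct_palatine
G_difficilis,MPPtQ,4e-04,1.62,none
G_fuliginosa,MDM,0.007,2.85,none
G_fuliginosa,MAMER,0.0163,2.13,indirect_jugal
G_fuliginosa,MAMEV,0.0035,1.41,indirect_jugal
G_fuliginosa,MAMEP,0.0069,1.46,indirect_jugal
G_fuliginosa,MAMOQ,0.001,2.02,indirect_jugal
G_fuliginosa,MPsTSl,0.002,1.12,indirect_jugal
G_fuliginosa,MPsTP,0.002,1.46,indirect_jugal
G_fuliginosa,MPtVl,0.0027,2.09,direct_palatine
G_fuliginosa,MPtVm,0.0036,1.99,direct_palatine
G_fuliginosa,MPtDl,0.0052,1.69,direct_palatine
G_fuliginosa,MPtDm,0.0032,2.1,direct_palatine
G_fuliginosa,MRPal,0.0014,2.6,direct_palatine
G_fuliginosa,MPPtQ,0.002,2.22,none
C_parvulus,MDM,0.0056,3.45,none
C_parvulus,MAMER,0.013,3.07,indirect_jugal
C_parvulus,MAMEV,0.0029,2.11,indirect_jugal
C_parvulus,MAMEP,0.0065,1.92,indirect_jugal
C_parvulus,MAMOQ,5e-04,1.44,indirect_jugal
C_parvulus,MPsTSl,0.0013,1.67,indirect_jugal
C_parvulus,MPsTP,0.0022,1.58,indirect_jugal
C_parvulus,MPtVl,0.0044,2.81,direct_palatine
C_parvulus,MPtVm,0.0016,2.81,direct_palatine
C_parvulus,MPtDl,0.0027,3.19,direct_palatine
C_parvulus,MPtDm,0.0029,2.75,direct_palatine
C_parvulus,MRPal,0.0012,3.18,direct_palatine
C_parvulus,MPPtQ,0.004,2.61,none
C_olivacea,MDM,0.0033,2.05,none
C_olivacea,MAMER,0.0041,1.74,indirect_jugal
C_olivacea,MAMEV,0.0011,1.14,indirect_jugal
C_olivacea,MAMEP,0.0022,1.33,indirect_jugal
C_olivacea,MPsTSl,7e-04,1.03,indirect_jugal
C_olivacea,MPsTP,5e-04,1.3,indirect_jugal
C_olivacea,MPtVl,0.0021,2.66,direct_palatine
C_olivacea,MPtVm,0.0014,2.27,direct_palatine
C_olivacea,MPtDl,8e-04,2.47,direct_palatine
C_olivacea,MPtDm,0.0016,1.86,direct_palatine
C_olivacea,MRPal,4e-04,1.8,direct_palatine
C_olivacea,MPPtQ,0.0019,1.86,none
G_scandens,MDM,0.015,3.89,none
G_scandens,MAMER,0.0329,2.52,indirect_jugal
G_scandens,MAMEV,0.009,1.89,indirect_jugal
G_scandens,MAMEP,0.0126,1.98,indirect_jugal
G_scandens,MAMOQ,0.0016,2.64,indirect_jugal
G_scandens,MPsTSl,0.0071,1.22,indirect_jugal
G_scandens,MPsTSm,0.0052,1.22,indirect_jugal
G_scandens,MPsTP,0.0168,1.54,indirect_jugal
G_scandens,MPtVl,0.0072,2.99,direct_palatine
G_scandens,MPtVm,0.0062,2.96,direct_palatine
G_scandens,MPtDl,0.0247,2.7,direct_palatine
G_scandens,MPtDm,0.0108,2.75,direct_palatine
G_scandens,MRPal,0.0057,2.6,direct_palatine
G_scandens,MPPtQ,0.0042,2.3,none
G_fortis,MDM,0.02,3.91,none
G_fortis,MAMER,0.0651,1.87,indirect_jugal
G_fortis,MAMEV,0.0159,1.85,indirect_jugal
G_fortis,MAMEP,0.0217,1.7,indirect_jugal
G_fortis,MAMOQ,0.0026,2.02,indirect_jugal
G_fortis,MPsTSl,0.0094,1.31,indirect_jugal
G_fortis,MPsTSm,0.0124,2.06,indirect_jugal
G_fortis,MPsTP,0.0283,3.58,indirect_jugal
G_fortis,MPtVl,0.0199,2.38,direct_palatine
G_fortis,MPtVm,0.0119,2.52,direct_palatine
G_fortis,MPtDl,0.0284,2.07,direct_palatine
G_fortis,MPtDm,0.0333,1.73,direct_palatine
G_fortis,MRPal,0.0041,2.88,direct_palatine
G_fortis,MPPtQ,0.0059,3.4,none
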