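activity_name,grav_x,grav_y,grav_z,f0_hz,amp_g,noise_g,met_mu,met_sigma
COMPUTER WORK,0.90,0.30,0.32,0.00,0.006,0.006,1.30,0.13
TV WATCHING,0.95,0.10,0.30,0.00,0.003,0.004,1.10,0.11
STANDING STILL,0.10,0.95,0.30,0.00,0.002,0.003,1.20,0.12
STAIR DESCENT,0.20,0.90,0.39,1.80,0.22,0.020,4.00,0.40
STAIR ASCENT,0.20,0.92,0.34,1.50,0.20,0.020,5.00,0.50
RAPID WALK,0.15,0.90,0.41,2.10,0.30,0.025,4.40,0.44
LEISURE WALK,0.18,0.92,0.35,1.70,0.20,0.020,3.30,0.33
WALKING AT RPE 5,0.16,0.91,0.38,1.90,0.25,0.022,4.00,0.40
WALKING AT RPE 1,0.20,0.93,0.31,1.50,0.16,0.018,3.00,0.30
STRENGTH EXERCISE CHEST PRESS,0.55,0.68,0.49,0.60,0.10,0.012,2.40,0.24
STRENGTH EXERCISE LEG CURL,0.65,0.60,0.47,0.60,0.09,0.012,2.20,0.22
STRETCHING YOGA,0.60,0.64,0.48,0.50,0.10,0.013,1.80,0.18
STRENGTH EXERCISE LEG EXTENSION,0.60,0.62,0.51,0.65,0.09,0.012,2.60,0.26
WASHING WINDOWS,0.40,0.80,0.45,0.90,0.18,0.018,3.20,0.32
DIGGING,0.30,0.75,0.59,0.80,0.25,0.022,4.60,0.46
IRONING,0.55,0.70,0.46,0.80,0.10,0.014,1.90,0.19
MOPPING,0.35,0.80,0.49,0.70,0.16,0.018,3.40,0.34
WASHING DISHES,0.60,0.65,0.47,0.70,0.08,0.012,1.80,0.18
REPLACING SHEETS ON A BED,0.45,0.70,0.55,0.60,0.17,0.018,3.30,0.33
HEAVY LIFTING,0.40,0.65,0.65,0.50,0.20,0.020,4.20,0.42
PERSONAL CARE,0.65,0.60,0.47,0.60,0.09,0.012,2.00,0.20
UNLOADING STORING DISHES,0.55,0.65,0.52,0.65,0.10,0.013,2.30,0.23
SWEEPING,0.35,0.82,0.45,0.85,0.15,0.016,3.10,0.31
VACUUMING,0.40,0.78,0.48,0.75,0.14,0.016,3.20,0.32
LIGHT GARDENING,0.35,0.70,0.62,0.55,0.13,0.016,3.00,0.30
SHOPPING,0.30,0.88,0.37,1.00,0.08,0.012,2.10,0.21
LIGHT HOME MAINTENANCE,0.50,0.68,0.54,0.65,0.14,0.016,3.10,0.31
PREPARE SERVE MEAL,0.60,0.62,0.51,0.55,0.08,0.012,2.00,0.20
LAUNDRY WASHING,0.50,0.72,0.48,0.60,0.09,0.012,2.10,0.21
YARD WORK,0.35,0.72,0.59,0.70,0.16,0.018,3.60,0.36
STRAIGHTENING UP DUSTING,0.55,0.68,0.49,0.75,0.11,0.014,3.00,0.30
TRASH REMOVAL,0.40,0.75,0.53,0.65,0.15,0.016,3.20,0.32
DRESSING,0.60,0.64,0.48,0.50,0.10,0.013,2.20,0.22
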