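temperature_c,pressure_mpa,water,ethanol,ethanol_water_70,ethanol_water_80,ethanol_water_90
65,25,991.17,773.97,815.53,795.68,789.11
65,21,989.51,770.51,812.59,780.99,783.22
65,17,987.83,766.77,809.48,789.13,779.69
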