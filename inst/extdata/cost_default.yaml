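# Operational cost configuration for the lab-scale SFE unit.
# Prices in Malaysian Ringgit (RM); consumption figures are per run.
sample_price: 70.0        # RM/kg dried herb
ethanol_price: 86.0       # RM per bottle
bottle_volume: 2.5        # L per bottle
co2_price: 224.0          # RM per cylinder
cylinder_mass: 30.0       # kg per cylinder
electricity_tariff: 0.365
tariff_unit: RM/kWh       # "sen/kWh" accepted, divided by 100 on load
labour_salary: 1800.0     # RM/month per operator
n_operators: 1
equipment_power:          # kW
  chiller: 13.82
  co2_pump: 0.75
  cosolvent_pump: 0.37
  bpr: 0.50
  oven: 0.80
  ambient: 0.60
annual_hours: 1920        # process equipment: 8 h/day x 240 days
equipment_hours:
  chiller: 5760           # continuous duty: 24 h x 240 days
runs_per_year: 240
sample_mass: 0.003        # kg per run (3 g charge)
co2_mass: 1.0             # kg per run
cosolvent_volume: 0.10    # L of co-solvent per run
run_duration: 2.0         # h per run
water_pct: 20.0           # % v/v water in ethanol
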