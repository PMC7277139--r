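# Packaged accident scenario: 40 t of benzyl chloride leaking for one hour
# from a petrochemical complex, starting at midnight on 1 January 2017.
release_mass: 40000        # kg
release_duration: 1        # hours
start_time: "2017-01-01 00:00:00"
horizon_days: 100
chemical:
  name: benzyl chloride
  molecular_weight: 126.58   # g/mol
  csf_oral: 0.17             # per mg/kg-day (oral, IRIS)
  background_air_ppb: 0.01
  air_decay_rate: 0.02       # per hour
  soil_decay_rate: 0.027     # per day
  deposition_velocity: 0.005 # m/s
  revolatilization_rate: 0.00005 # per day
grid:
  nx: 160
  ny: 120
  dx: 100
  dy: 100
  mixing_height: 10
  origin: [0, 0]
  source_cell: [40, 90]
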