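# Economic evaluation settings (USD; cycle length one year)
discount_rate: 0.03
n_cycles: 60
cycle_length_months: 12
wtp: 27931.04
fx_rate: 6.93          # CNY per USD
fare_per_visit: 80     # CNY, taxi fare per hospital visit
annual_wage: 9338.67   # USD per year, Sichuan average wage
half_cycle_correction: true
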