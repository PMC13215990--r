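total_population: 678243.0
start_age: 6.0
end_age: 12.0
dt: 1.0
discount_rate: 0.0
initial_stocks:
  caries_free: 440175.633012516133022
  caries_untreated: 99452.792276409396436
  filled: 71.274421769281929
  endodontic: 49.445928102881481
  missing: 138493.854361202305881
  cum_fillings: 82673.206687277794117
  cum_endodontic: 5463.172228432100383
  cum_extractions: 319.174886856497437
fractions:
  caries_fraction: 0.140932929469746
  fill_fraction: 0.014511268474036
  endo_fraction: 0.004325997451541
  extract_fraction: 0.098675251569408
  recur_filled_fraction: 0.000150800061889
  recur_endo_fraction: 0.000107972839848
interventions:
  stb:
    effectiveness: 0.1
    coverage: 0.95
    unit_cost: 57.600000000000001
    onset_lag: 0.0
  sealant:
    effectiveness: 0.58
    coverage: 0.27
    unit_cost: 203.5
    onset_lag: 0.0
unit_costs:
  filling:
    mean: 360.100000000000023
    min: 270.199999999999989
    max: 471.5
  endodontic:
    mean: 1839.400000000000091
    min: 1315.700000000000045
    max: 2619.699999999999818
  extraction:
    mean: 133.599999999999994
    min: 100.5
    max: 155.900000000000006
  stb:
    mean: 57.600000000000001
    min: 34.799999999999997
    max: 80.400000000000006
  sealant:
    mean: 203.5
    min: 92.200000000000003
    max: 366.800000000000011
exchange_rate: 32.0
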