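# iscsim protocol
name typical_5day_isc
duration_h 120
seed 1
dt_s 1
record_s 60

[stage lingering]
time_h 12
duration_min 40

[stage lingering]
time_h 26.4
duration_min 40

[stage lingering]
time_h 84
duration_min 40

[stage pump_inhibition]
time_h 96
factor 0.04
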