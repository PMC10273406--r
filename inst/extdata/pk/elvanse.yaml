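# Lisdexamfetamine extended-release (Elvanse) exposure parameters for the
# vLDX models. Oral bioavailability 0.964; absorption and clearance chosen
# to give amfetamine-like kinetics (t1/2 ~ 5 h) with renal elimination.
name: vLDX
F_oral: 0.964
ka: 0.8        # 1/h
CL: 25         # L/h, reference 70 kg adult, renal
Kp: 3          # tissue:plasma partition, all tissues
dose: 50       # mg
doses_per_day: 1
days: 7
ec50: 0.1      # mg/L, effect-site half-occupancy
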