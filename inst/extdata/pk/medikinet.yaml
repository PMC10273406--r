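# Methylphenidate modified-release (Medikinet) exposure parameters for the
# vMPH models. Oral bioavailability 0.30; short half-life (~2 h), twice-daily
# dosing, renal elimination.
name: vMPH
F_oral: 0.30
ka: 1.5
CL: 40
Kp: 2
dose: 20
doses_per_day: 2
days: 7
ec50: 0.02
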