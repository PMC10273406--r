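# Methylphenidate osmotic-release (Concerta/OROS) exposure parameters.
# Oral bioavailability 0.32; slow zero-order-like release approximated by a
# small first-order absorption rate, once-daily dosing.
name: vMPH_oros
F_oral: 0.32
ka: 0.25
CL: 40
Kp: 2
dose: 36
doses_per_day: 1
days: 7
ec50: 0.02
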