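motive	gene	sign
neurotransmitter imbalance	SYN01	1
neurotransmitter imbalance	SYN02	-1
neurotransmitter imbalance	SYN03	1
neurotransmitter imbalance	SYN04	1
neurotransmitter imbalance	SYN05	-1
neuroinflammation	SYN06	1
neuroinflammation	SYN07	1
neuroinflammation	SYN08	-1
neuroinflammation	SYN09	1
neuroinflammation	SYN10	1
circadian system imbalance	SYN11	-1
circadian system imbalance	SYN12	1
circadian system imbalance	SYN13	-1
circadian system imbalance	SYN14	1
circadian system imbalance	SYN15	1
altered neural viability	SYN16	-1
altered neural viability	SYN17	1
altered neural viability	SYN18	-1
altered neural viability	SYN19	-1
altered neural viability	SYN20	1
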