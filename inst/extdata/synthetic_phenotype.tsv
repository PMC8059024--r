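subject	response	group	time	status
S01	-0.9502	ctrl	4.4308	1
S02	0.4771	ctrl	1.0129	1
S03	1.9159	ctrl	0.5357	1
S04	-2.2078	ctrl	20.4697	0
S05	0.6823	ctrl	1.2627	0
S06	0.6798	ctrl	0.8099	0
S07	-0.7634	case	1.9395	0
S08	-0.4978	case	1.1658	1
S09	0.2549	case	3.4804	1
S10	-1.3278	case	0.2687	1
S11	-0.4163	case	1.7026	1
S12	-0.3173	case	3.1632	1
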