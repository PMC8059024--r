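	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12
GENE01	-1.0296	0.2514	0.9865	-2.6702	-0.1258	0.9307	-0.5636	-0.1311	-1.1866	-0.8055	-0.1406	-1.0115
GENE02	-1.3028	-0.1135	2.1135	-1.9704	1.3412	0.5461	-0.8904	-1.3033	-0.8825	-0.7769	0.0297	-0.872
GENE03	-1.793	0.6118	0.2594	-2.5286	0.2711	-0.4681	-0.1147	-0.8581	-0.7315	-0.1925	-0.1589	-1.0526
GENE04	-0.5238	-0.4968	-1.806	-0.5821	-1.1089	-1.015	-0.1623	0.5631	1.6478	-0.7734	1.6059	-1.1578
GENE05	0.6566	2.549	-0.0348	-0.6696	-0.0076	1.7771	-1.1386	1.3678	1.3296	0.3365	0.0069	-0.4555
GENE06	-0.3665	0.6483	2.0703	-0.1534	-1.3907	-0.7236	0.2583	-0.3171	-0.1778	-0.17	-1.3723	-0.1738
GENE07	0.8502	0.6976	0.55	-0.4027	-0.1916	-1.1945	-0.0532	0.2552	1.706	1.0015	-0.4956	0.3556
GENE08	-1.1346	0.8782	0.9729	2.1211	0.4145	-0.4747	0.066	-0.5025	-0.826	0.167	-0.8963	0.1682
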