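metric	cohort	numerator	denominator
rare_any	patients	115	1376
rare_any	controls	59	976
missense	patients	101	1376
missense	controls	50	976
splice	patients	10	1376
splice	controls	7	976
indel	patients	4	1376
indel	controls	2	976
compound_het	patients	11	1376
compound_het	controls	5	976
apoe_e4_missense_carriers	patients	66	96
apoe_e4_full_cohort	patients	790	1350
familial_history_missense	patients	43	73
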