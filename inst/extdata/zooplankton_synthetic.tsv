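species_id	count
taxon_01	64
taxon_02	42
taxon_03	35
taxon_04	29
taxon_05	29
taxon_06	29
taxon_07	30
taxon_08	24
taxon_09	15
taxon_10	23
taxon_11	18
taxon_12	17
taxon_13	17
taxon_14	14
taxon_15	17
taxon_16	13
taxon_17	15
taxon_18	15
taxon_19	17
taxon_20	12
taxon_21	17
taxon_22	6
taxon_23	6
taxon_24	7
taxon_25	7
taxon_26	7
taxon_27	12
taxon_28	8
taxon_29	10
taxon_30	6
taxon_31	8
taxon_32	6
taxon_33	4
taxon_34	3
taxon_35	4
taxon_36	3
taxon_37	5
taxon_38	3
taxon_39	3
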