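species	group	bv_cm3	rnp_r	rnp_l	rnm_r	rnm_l	n	source_row
Homo sapiens	humans	1235.7	289.9	293.1	3.1	3.0	10	1
Gorilla gorilla	non-human apes	98.8	33.7	34.3	2.6	2.0	1	2
Hylobates lar	non-human apes	396.8	131.1	129.3	6.8	7.4	2	3
Pan paniscus	non-human apes	354.8	141.3	124.5	7.9	6.0	2	4
Pan troglodytes	non-human apes	368.9	100.2	101.7	4.4	4.9	3	5
Pongo pygmaeus	non-human apes	364.3	123.7	127.9	1.5	3.0	3	6
Lophocebus albigena	old world monkeys	53.6	8.7	9.9	7.6	7.7	1	7
Cercopithecus Spec	old world monkeys	90.1	19.0	18.6	7.1	7.9	1	8
Macaca fascicularis	old world monkeys	84.3	33.6	35.6	15.1	13.8	1	9
Macaca mulatta	old world monkeys	64.9	10.9	11.8	6.3	6.1	1	10
Aotus trivirgatus	new world monkeys	16.9	1.5	1.8	4.6	4.3	1	11
Callithrix jacchus	new world monkeys	15.2	1.6	1.5	3.1	2.8	1	12
Saimiri scuireus	new world monkeys	9.0	0.3	0.2	1.3	1.4	1	13
Daubentonia madagescariensis	prosimians	22.6	2.5	3.2	5.6	5.3	1	14
Galago senegalensis	prosimians	8.0	0.3	0.3	2.2	2.4	1	15
Indri indri	prosimians	36.4	2.8	2.8	4.9	4.8	1	16
Lemur catta	prosimians	46.7	6.8	8.3	6.5	6.3	1	17
Lepilemur ruficaudatus	prosimians	12.1	0.9	0.9	2.8	2.7	1	18
Nycticebus coucang	prosimians	2.8	0.8	0.7	1.1	1.1	1	19
Tarsius bancanus	prosimians	3.0	0.9	0.8	0.7	0.8	1	20
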