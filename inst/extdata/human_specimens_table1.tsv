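id	section_plane	sex	age	fresh_weight_g	mapped	source_row
pm15	Horizontal	Male	54	1260	TRUE	1
pm16	Horizontal	Male	63	1340	TRUE	2
pm6	Coronal	Male	54	1622	TRUE	3
pm7	Coronal	Male	37	1437	TRUE	4
pm11	Coronal	Male	74	1381	TRUE	5
pm5	Coronal	Female	59	1142	TRUE	6
pm8	Coronal	Female	72	1216	TRUE	7
pm9	Coronal	Female	79	1110	TRUE	8
pm10	Coronal	Female	85	1046	TRUE	9
pm12	Coronal	Female	43	1198	TRUE	10
pm20	Coronal	Male	65	1392	FALSE	11
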