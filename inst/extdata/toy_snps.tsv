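sample	species	population	snp_id	locus_id	pos_in_locus	gt
s01	X	X	snp_h06	La	1	1
s02	X	X	snp_h06	La	1	1
s03	X	X	snp_h06	La	1	1
s04	X	X	snp_h06	La	1	1
s05	X	X	snp_h06	La	1	1
s06	Y	Y	snp_h06	La	1	1
s07	Y	Y	snp_h06	La	1	0
s08	Y	Y	snp_h06	La	1	0
s09	Y	Y	snp_h06	La	1	0
s10	Y	Y	snp_h06	La	1	0
s01	X	X	snp_maf3	Lb	1	1
s02	X	X	snp_maf3	Lb	1	1
s03	X	X	snp_maf3	Lb	1	1
s04	X	X	snp_maf3	Lb	1	0
s05	X	X	snp_maf3	Lb	1	0
s06	Y	Y	snp_maf3	Lb	1	0
s07	Y	Y	snp_maf3	Lb	1	0
s08	Y	Y	snp_maf3	Lb	1	0
s09	Y	Y	snp_maf3	Lb	1	0
s10	Y	Y	snp_maf3	Lb	1	0
s01	X	X	snp_maf2	Lc	1	1
s02	X	X	snp_maf2	Lc	1	1
s03	X	X	snp_maf2	Lc	1	0
s04	X	X	snp_maf2	Lc	1	0
s05	X	X	snp_maf2	Lc	1	0
s06	Y	Y	snp_maf2	Lc	1	0
s07	Y	Y	snp_maf2	Lc	1	0
s08	Y	Y	snp_maf2	Lc	1	0
s09	Y	Y	snp_maf2	Lc	1	0
s10	Y	Y	snp_maf2	Lc	1	0
s01	X	X	snp_miss	Ld	1	1
s02	X	X	snp_miss	Ld	1	1
s03	X	X	snp_miss	Ld	1	1
s04	X	X	snp_miss	Ld	1	0
s05	X	X	snp_miss	Ld	1	0
s06	Y	Y	snp_miss	Ld	1	0
s07	Y	Y	snp_miss	Ld	1	NA
s08	Y	Y	snp_miss	Ld	1	NA
s09	Y	Y	snp_miss	Ld	1	NA
s10	Y	Y	snp_miss	Ld	1	NA
s01	X	X	snp_le1	Le	1	0
s02	X	X	snp_le1	Le	1	0
s03	X	X	snp_le1	Le	1	0
s04	X	X	snp_le1	Le	1	0
s05	X	X	snp_le1	Le	1	1
s06	Y	Y	snp_le1	Le	1	1
s07	Y	Y	snp_le1	Le	1	1
s08	Y	Y	snp_le1	Le	1	0
s09	Y	Y	snp_le1	Le	1	0
s10	Y	Y	snp_le1	Le	1	0
s01	X	X	snp_le2	Le	2	0
s02	X	X	snp_le2	Le	2	0
s03	X	X	snp_le2	Le	2	1
s04	X	X	snp_le2	Le	2	1
s05	X	X	snp_le2	Le	2	1
s06	Y	Y	snp_le2	Le	2	0
s07	Y	Y	snp_le2	Le	2	0
s08	Y	Y	snp_le2	Le	2	0
s09	Y	Y	snp_le2	Le	2	0
s10	Y	Y	snp_le2	Le	2	0
s01	X	X	snp_le3	Le	3	2
s02	X	X	snp_le3	Le	3	2
s03	X	X	snp_le3	Le	3	2
s04	X	X	snp_le3	Le	3	0
s05	X	X	snp_le3	Le	3	0
s06	Y	Y	snp_le3	Le	3	0
s07	Y	Y	snp_le3	Le	3	0
s08	Y	Y	snp_le3	Le	3	0
s09	Y	Y	snp_le3	Le	3	0
s10	Y	Y	snp_le3	Le	3	0
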