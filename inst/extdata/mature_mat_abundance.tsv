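# Relative abundance (%) of phylotypes in mature (0.5-2 cm) Fe(III)-oxide
# mats from two acidic springs, by random shotgun sequencing (three
# technologies) and by 16S rRNA gene amplicon (iTag) sequencing of matching
# samples. NA = not detected/reported.
taxon	osp_454	osp_illumina	osp_itag	beowulf_sanger	beowulf_454	beowulf_illumina	beowulf_itag
M_yellowstonensis	10.3	16	0.51	3.9	6.6	12	NA
Hydrogenobaculum	3.4	3	24.2	2	1.2	4.3	14
Geoarchaeota	43.4	33	41	1	3	6	4
NAG2	4	6	24	26	38	27	42
Thaumarchaeota	0.4	0.4	3	19	4.4	2	3.2
NAG3	0.1	0.12	NA	4	3	5	26
Other_Sulfolobales	2.5	4	3.3	3.9	10	11	8.5
Nanoarchaeota	0.2	0.6	NA	0	0.1	0.6	NA
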