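# Clinical/demographic case counts for the 250 primary glioma diagnoses of
# the TCGA G-CIMP cohort (G-CIMP-high n = 234, G-CIMP-low n = 16).
variable	category	gcimp_high	gcimp_low
cases	total	234	16
age	under_40	149	10
age	over_40	80	6
age	unknown	5	0
gender	male	133	7
gender	female	100	9
gender	unknown	1	0
histology_2007	oligodendroglioma	39	0
histology_2007	oligoastrocytoma	74	1
histology_2007	astrocytoma	118	10
histology_2007	glioblastoma	2	5
who_grade	grade_2	111	3
who_grade	grade_3	92	8
who_grade	grade_4	2	5
who_2016	idh_mutant_astrocytoma	232	11
who_2016	idh_mutant_glioblastoma	2	5
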