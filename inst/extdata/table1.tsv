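family_id	parental_origin	sanger_screening	chromosome	position	ref	alt	exon	proband_mddpcr	proband_pasm	control_mddpcr	control_pasm	father_mddpcr	father_pasm	mother_mddpcr	mother_pasm	father_sperm	oral_epithelium	saliva	hair_follicle	urine	blood_called	sperm_called
DS001	Paternal	Detectable	2	166904194	T	-	Exon8	50.39%	49.20%	0.00%	0.80%	28.59%	32.60%	0.00%	5.60%	39.04%	NA	21.44%	34.43%	35.89%	TRUE	TRUE
DS003	Paternal	Detectable	2	166894639	C	T	Exon15	49.29%	46.10%	0.01%	0.12%	19.43%	18.21%	0.01%	ND	23.19%	11.19%	19.70%	11.93%	14.16%	TRUE	TRUE
DS017	paternal	Undetectable	2	166848438	G	A	Exon26	49.19%(16.40%)	52.90%	0.00%(0.00%)	0.00%	4.36%(1.45%)	4.00%	0.01%(0.00%)	0.00%	7.52%(2.51%)	NA	2.58%(0.86%)	3.85%(1.28%)	NA	TRUE	TRUE
DS101	paternal	Undetectable	2	166848230	T	C	Exon26	50.05%	46.17%	0.00%	0.10%	6.31%	6.10%	0.00%	0.10%	8.48%	15.70%	5.96%	5.55%	11.18%	TRUE	TRUE
DS166	paternal	Undetectable	2	166894396	C	T	Exon15	44.46%(11.11%)	52.40%	0.00%(0.00%)	0.10%	2.94%(0.74%)	3.10%	0.01%(0.00%)	0.20%	23.80%(5.29%)	NA	2.27%(0.57%)	NA	NA	TRUE	TRUE
DS203	paternal	Undetectable	2	166894440	G	A	Exon15	49.67%	53.52%	0.00%	0.00%	0.00%	0.10%	0.00%	0.10%	0.04%	0.04%	1.27%	0.04%	0.12%	FALSE	TRUE
DS312	paternal	Undetectable	2	166900371	GA	-	Exon11	49.87%	43.90%	0.02%	0.30%	13.59%	11.60%	0.02%	0.10%	18.02%	10.48%	11.79%	10.94%	12.31%	TRUE	TRUE
DS314	paternal	Undetectable	2	166895938	C	T	Exon14	49.63%	41.40%	0.04%	0.10%	14.36%	7.50%	0.01%	0.00%	25.12%	11.73%	14.02%	18.66%	12.37%	TRUE	TRUE
DS296	paternal	Undetectable	2	166904178	C	T	Exon8	49.93%	50.00%	0.00%	0.30%	0.01%	0.00%	0.00%	0.00%	0.31%	NA	NA	NA	NA	FALSE	TRUE
DS308	paternal	Undetectable	2	166852541	CT	-	Exon24	49.87%	52.90%	0.00%	0.20%	0.00%	0.30%	0.00%	0.00%	0.03%	NA	NA	NA	NA	FALSE	TRUE
DS035	paternal	Undetectable	2	166894440	G	A	Exon15	50.01%	52.24%	0.00%	0.00%	10.24%	15.00%	0.01%	0.20%	NA	NA	NA	NA	NA	TRUE	NA
DS094	paternal	Undetectable	2	166848852	C	T	Exon26	46.68%(15.94%)	46.10%	0.00%(0.00%)	0.00%	1.33%(0.44%)	1.30%	0.02%(0.00%)	0.00%	NA	NA	NA	NA	NA	TRUE	NA
DS164	paternal	Undetectable	2	166915194	T	C	Exon2	49.15%	50.00%	0.00%	0.00%	9.32%	8.60%	0.00%	0.00%	NA	NA	NA	NA	NA	TRUE	NA
DS125	paternal	Undetectable	2	166868765	C	T	Exon19	49.99%	47.23%	0.00%	0.30%	7.15%	6.60%	0.01%	0.60%	NA	NA	NA	NA	NA	TRUE	NA
DS280	paternal	Undetectable	2	166866246	C	T	Exon20	50.14%	49.50%	0.01%	0.10%	3.52%	4.30%	0.01%	9.70%	NA	NA	NA	NA	NA	TRUE	NA
DS324	paternal	Detectable	2	166892659	CA	-	Exon16	50.24%	60.35%	0.00%	3.59%	11.01%	15.23%	0.00%	4.15%	NA	NA	NA	NA	NA	TRUE	NA
DS328	paternal	Detectable	2	166904273	C	T	Exon8	50.16%	49.88%	0.00%	0.01%	29.00%	27.41%	0.01%	0.00%	NA	NA	NA	NA	NA	TRUE	NA
DS329	paternal	Detectable	2	166911262	C	T	Exon4	50.05%	47.36%	0.00%	0.00%	34.51%	31.37%	0.00%	0.00%	NA	NA	NA	NA	NA	TRUE	NA
DS004	maternal	Detectable	2	166848782	C	G	Exon26	51.91%(13.02%)	56.10%	0.02%(0.00%)	0.00%	0.00%(0.00%)	0.00%	19.40%(4.87%)	21.20%	NA	17.56%(4.39%)	18.34%(4.58%)	25.60%(6.40%)	17.54%(4.39%)	TRUE	FALSE
DS276	maternal	Undetectable	2	166904178	C	T	Exon8	50.07%	49.72%	0.00%	0.30%	0.00%	0.70%	0.82%	1.70%	0.01%	0.73%	0.94%	0.00%	0.10%	TRUE	FALSE
DS287	maternal	Detectable	2	166901753	AAGTT	-	Exon10	49.96%	51.70%	0.00%	0.00%	0.00%	0.20%	32.81%	32.90%	NA	35.92%	33.61%	45.65%	39.23%	TRUE	FALSE
DS307	maternal	Detectable	2	166905453	A	C	Exon6	49.66%	46.13%	0.00%	0.20%	0.01%	0.00%	25.67%	24.35%	NA	22.16%	NA	8.83%	16.68%	TRUE	FALSE
DS128	maternal	Undetectable	2	166868765	C	T	Exon19	49.36%	49.24%	0.00%	0.30%	0.00%	0.10%	13.00%	13.20%	0.01%	10.37%	12.29%	6.24%	0.65%	TRUE	FALSE
DS306	maternal	Undetectable	2	166894396	C	T	Exon15	50.00%(12.25%)	48.99%	0.00%(0.00%)	0.10%	0.02%(0.01%)	0.90%	0.06%(0.02%)	0.10%	0.04%(0.01%)	NA	NA	NA	NA	TRUE	FALSE
DS136	maternal	Undetectable	2	166859043	G	A	Exon21	49.70%	46.88%	0.00%	0.00%	0.00%	0.30%	11.71%	9.20%	NA	NA	NA	NA	NA	TRUE	NA
DS152	maternal	Undetectable	2	166898844	C	T	Exon12	49.79%	47.87%	0.00%	0.20%	0.00%	0.10%	2.15%	0.40%	NA	NA	NA	NA	NA	TRUE	NA
DS316	maternal	Detectable	2	166848864	G	A	Exon26	49.89%	50.70%	0.01%	0.10%	0.01%	0.00%	20.28%	20.30%	NA	NA	NA	NA	NA	TRUE	NA
DS323	maternal	Detectable	2	166854686	G	A	Exon22	49.79%	47.97%	0.00%	0.10%	0.00%	0.05%	23.14%	23.42%	NA	NA	NA	NA	NA	TRUE	NA
DS327	maternal	Detectable	2	166894436	C	G	Exon15	49.88%	49.08%	0.00%	0.00%	0.00%	0.00%	24.18%	23.94%	NA	NA	NA	NA	NA	TRUE	NA
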