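microcosm_id	time_days	analyte	value	unit
NF_FER_C13	0	fe2	74.8308985278687	umol_per_g
NF_FER_C13	0.5	fe2	88.8915294990745	umol_per_g
NF_FER_C13	1	fe2	91.7854723449742	umol_per_g
NF_FER_C13	1.5	fe2	94.6038881946267	umol_per_g
NF_FER_C13	2	fe2	105.761070761686	umol_per_g
NF_FER_C13	3	fe2	115.706770070243	umol_per_g
NF_FER_C13	4	fe2	129.380078340056	umol_per_g
NF_FER_C13	0	total_fe	154.510945264227	umol_per_g
NF_FER_C13	0.5	total_fe	155.828692783129	umol_per_g
NF_FER_C13	1	total_fe	153.987584234066	umol_per_g
NF_FER_C13	1.5	total_fe	155.321539188565	umol_per_g
NF_FER_C13	2	total_fe	155.46615382597	umol_per_g
NF_FER_C13	3	total_fe	156.760949431344	umol_per_g
NF_FER_C13	4	total_fe	155.928184783439	umol_per_g
NF_FER_C13	0	acetate	3.26449749320957	umol_per_g
NF_FER_C13	0.5	acetate	1.18500146111613	umol_per_g
NF_FER_C13	1	acetate	0.319143223630743	umol_per_g
NF_FER_C13	1.5	acetate	3.47306715029138	umol_per_g
NF_FER_C13	2	acetate	1.15179321081719	umol_per_g
NF_FER_C13	3	acetate	3.164931035451	umol_per_g
NF_FER_C13	4	acetate	0.445385336558669	umol_per_g
NF_FER_C13	0	ch4_total	0.212556631246913	umol
NF_FER_C13	0.5	ch4_total	1.42120454262606	umol
NF_FER_C13	1	ch4_total	1.7728596112302	umol
NF_FER_C13	1.5	ch4_total	2.85475235149423	umol
NF_FER_C13	2	ch4_total	3.77221668717929	umol
NF_FER_C13	3	ch4_total	5.4966339571264	umol
NF_FER_C13	4	ch4_total	7.6222347558218	umol
NF_FER_C13	0	co2_total	0.140171688529654	umol
NF_FER_C13	0.5	co2_total	11.0380296744154	umol
NF_FER_C13	1	co2_total	15.3207883432899	umol
NF_FER_C13	1.5	co2_total	16.825829238293	umol
NF_FER_C13	2	co2_total	28.4626965276815	umol
NF_FER_C13	3	co2_total	33.6584342930634	umol
NF_FER_C13	4	co2_total	50.4502177142404	umol
NF_FER_C13	0	atom13_ch4	0.375625781630026	percent
NF_FER_C13	0.5	atom13_ch4	82.8686889645073	percent
NF_FER_C13	1	atom13_ch4	77.7914019405679	percent
NF_FER_C13	1.5	atom13_ch4	69.425226850846	percent
NF_FER_C13	2	atom13_ch4	76.1130192502053	percent
NF_FER_C13	3	atom13_ch4	72.0672389670424	percent
NF_FER_C13	4	atom13_ch4	74.1902831463026	percent
NF_FER_C13	0	atom13_co2	0	percent
NF_FER_C13	0.5	atom13_co2	96.2927292339106	percent
NF_FER_C13	1	atom13_co2	94.642623173137	percent
NF_FER_C13	1.5	atom13_co2	95.0172734420482	percent
NF_FER_C13	2	atom13_co2	96.0924139981438	percent
NF_FER_C13	3	atom13_co2	94.0101235115445	percent
NF_FER_C13	4	atom13_co2	94.8012000316763	percent
NF_FER_C13	0	ph	7.65548365785183	ph
NF_FER_C13	0.5	ph	7.66549234156216	ph
NF_FER_C13	1	ph	7.69176586514551	ph
NF_FER_C13	1.5	ph	7.71733703008584	ph
NF_FER_C13	2	ph	7.65809292060269	ph
NF_FER_C13	3	ph	7.72247173148494	ph
NF_FER_C13	4	ph	7.66846439909231	ph
NF_CTR_C13	0	fe2	55.3805346326118	umol_per_g
NF_CTR_C13	0.5	fe2	56.6554077579749	umol_per_g
NF_CTR_C13	1	fe2	59.1900951967701	umol_per_g
NF_CTR_C13	1.5	fe2	58.807549523052	umol_per_g
NF_CTR_C13	2	fe2	57.8301227656951	umol_per_g
NF_CTR_C13	3	fe2	57.7067176928009	umol_per_g
NF_CTR_C13	4	fe2	58.4427593782476	umol_per_g
NF_CTR_C13	0	total_fe	63.2707843527295	umol_per_g
NF_CTR_C13	0.5	total_fe	64.1771010601534	umol_per_g
NF_CTR_C13	1	total_fe	60.9702531393192	umol_per_g
NF_CTR_C13	1.5	total_fe	65.9749473093898	umol_per_g
NF_CTR_C13	2	total_fe	64.8577075567391	umol_per_g
NF_CTR_C13	3	total_fe	64.8009260942091	umol_per_g
NF_CTR_C13	4	total_fe	64.3442248263197	umol_per_g
NF_CTR_C13	0	acetate	3.26582697795591	umol_per_g
NF_CTR_C13	0.5	acetate	1.96247793648569	umol_per_g
NF_CTR_C13	1	acetate	0.977880663734911	umol_per_g
NF_CTR_C13	1.5	acetate	4.29949317514985	umol_per_g
NF_CTR_C13	2	acetate	2.19641093201499	umol_per_g
NF_CTR_C13	3	acetate	4.28029852798104	umol_per_g
NF_CTR_C13	4	acetate	1.65821314312834	umol_per_g
NF_CTR_C13	0	ch4_total	0	umol
NF_CTR_C13	0.5	ch4_total	2.19144602708212	umol
NF_CTR_C13	1	ch4_total	3.96037893531546	umol
NF_CTR_C13	1.5	ch4_total	5.25754896320288	umol
NF_CTR_C13	2	ch4_total	8.41773590165328	umol
NF_CTR_C13	3	ch4_total	11.7835810403899	umol
NF_CTR_C13	4	ch4_total	17.0904657749284	umol
NF_CTR_C13	0	co2_total	0.327614712478553	umol
NF_CTR_C13	0.5	co2_total	3.81410393455328	umol
NF_CTR_C13	1	co2_total	5.66528038749917	umol
NF_CTR_C13	1.5	co2_total	6.57598388287998	umol
NF_CTR_C13	2	co2_total	10.1363314220866	umol
NF_CTR_C13	3	co2_total	14.44798196823	umol
NF_CTR_C13	4	co2_total	21.4083680476711	umol
NF_CTR_C13	0	atom13_ch4	3.21698139694073	percent
NF_CTR_C13	0.5	atom13_ch4	91.2574985319933	percent
NF_CTR_C13	1	atom13_ch4	87.1331551456213	percent
NF_CTR_C13	1.5	atom13_ch4	85.3455417640558	percent
NF_CTR_C13	2	atom13_ch4	90.5604155604896	percent
NF_CTR_C13	3	atom13_ch4	86.9189582766621	percent
NF_CTR_C13	4	atom13_ch4	87.556631137407	percent
NF_CTR_C13	0	atom13_co2	0.189867355065819	percent
NF_CTR_C13	0.5	atom13_co2	91.1043321997981	percent
NF_CTR_C13	1	atom13_co2	90.0916560870448	percent
NF_CTR_C13	1.5	atom13_co2	86.8689893110812	percent
NF_CTR_C13	2	atom13_co2	92.3825311665773	percent
NF_CTR_C13	3	atom13_co2	87.7480697847938	percent
NF_CTR_C13	4	atom13_co2	90.1306699333781	percent
NF_CTR_C13	0	ph	7.58302968558726	ph
NF_CTR_C13	0.5	ph	7.64181129464908	ph
NF_CTR_C13	1	ph	7.63250177402555	ph
NF_CTR_C13	1.5	ph	7.56305864438178	ph
NF_CTR_C13	2	ph	7.59744022531614	ph
NF_CTR_C13	3	ph	7.57725019810169	ph
NF_CTR_C13	4	ph	7.61597506672158	ph
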