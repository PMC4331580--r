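microcosm_id	domain	fraction_index	buoyant_density_g_per_ml	copies
NF_FER_C13_bac	Bacteria	1	1.82	20.9256686158183
NF_FER_C13_bac	Bacteria	2	1.81615384615385	1491.14566513791
NF_FER_C13_bac	Bacteria	3	1.81230769230769	33843.6824843361
NF_FER_C13_bac	Bacteria	4	1.80846153846154	578220.789350522
NF_FER_C13_bac	Bacteria	5	1.80461538461538	2771247.40296191
NF_FER_C13_bac	Bacteria	6	1.80076923076923	12735096.2330919
NF_FER_C13_bac	Bacteria	7	1.79692307692308	24045658.4688838
NF_FER_C13_bac	Bacteria	8	1.79307692307692	19857773.4815216
NF_FER_C13_bac	Bacteria	9	1.78923076923077	6868857.44150987
NF_FER_C13_bac	Bacteria	10	1.78538461538462	10850296.3521132
NF_FER_C13_bac	Bacteria	11	1.78153846153846	12717828.4375441
NF_FER_C13_bac	Bacteria	12	1.77769230769231	8653173.61615613
NF_FER_C13_bac	Bacteria	13	1.77384615384615	1969098.23312097
NF_FER_C13_bac	Bacteria	14	1.77	285569.658174939
NF_FER_C12_bac	Bacteria	1	1.82	9.04274704614527e-13
NF_FER_C12_bac	Bacteria	2	1.81615384615385	6.41605784313844e-09
NF_FER_C12_bac	Bacteria	3	1.81230769230769	1.49104024006556e-05
NF_FER_C12_bac	Bacteria	4	1.80846153846154	0.0113164881877238
NF_FER_C12_bac	Bacteria	5	1.80461538461538	5.42632237771973
NF_FER_C12_bac	Bacteria	6	1.80076923076923	677.113746992652
NF_FER_C12_bac	Bacteria	7	1.79692307692308	35997.6388865023
NF_FER_C12_bac	Bacteria	8	1.79307692307692	1107898.95553643
NF_FER_C12_bac	Bacteria	9	1.78923076923077	8415717.2333801
NF_FER_C12_bac	Bacteria	10	1.78538461538462	24054700.8177128
NF_FER_C12_bac	Bacteria	11	1.78153846153846	45910434.3854272
NF_FER_C12_bac	Bacteria	12	1.77769230769231	20371476.3121774
NF_FER_C12_bac	Bacteria	13	1.77384615384615	5373845.66035912
NF_FER_C12_bac	Bacteria	14	1.77	411693.060454164
NF_FER_C13_arc	Archaea	1	1.82	9.18323698701626e-13
NF_FER_C13_arc	Archaea	2	1.81615384615385	4.73800640016947e-09
NF_FER_C13_arc	Archaea	3	1.81230769230769	1.4370053555471e-05
NF_FER_C13_arc	Archaea	4	1.80846153846154	0.0123276856753387
NF_FER_C13_arc	Archaea	5	1.80461538461538	4.19298284925888
NF_FER_C13_arc	Archaea	6	1.80076923076923	744.166290139684
NF_FER_C13_arc	Archaea	7	1.79692307692308	43873.7230150243
NF_FER_C13_arc	Archaea	8	1.79307692307692	873906.396483316
NF_FER_C13_arc	Archaea	9	1.78923076923077	7129138.95681957
NF_FER_C13_arc	Archaea	10	1.78538461538462	19961360.1375467
NF_FER_C13_arc	Archaea	11	1.78153846153846	30039144.2623244
NF_FER_C13_arc	Archaea	12	1.77769230769231	24918596.2995945
NF_FER_C13_arc	Archaea	13	1.77384615384615	4340230.32993372
NF_FER_C13_arc	Archaea	14	1.77	540319.572219688
NF_FER_C12_arc	Archaea	1	1.82	9.38786414264474e-13
NF_FER_C12_arc	Archaea	2	1.81615384615385	5.38333719382406e-09
NF_FER_C12_arc	Archaea	3	1.81230769230769	1.66348595531604e-05
NF_FER_C12_arc	Archaea	4	1.80846153846154	0.00867338941164464
NF_FER_C12_arc	Archaea	5	1.80461538461538	3.45244438145181
NF_FER_C12_arc	Archaea	6	1.80076923076923	570.297625286304
NF_FER_C12_arc	Archaea	7	1.79692307692308	32635.3452645359
NF_FER_C12_arc	Archaea	8	1.79307692307692	805118.627063465
NF_FER_C12_arc	Archaea	9	1.78923076923077	6747114.81336308
NF_FER_C12_arc	Archaea	10	1.78538461538462	19614238.4343955
NF_FER_C12_arc	Archaea	11	1.78153846153846	45227010.3771618
NF_FER_C12_arc	Archaea	12	1.77769230769231	18791594.8530019
NF_FER_C12_arc	Archaea	13	1.77384615384615	3792733.33977659
NF_FER_C12_arc	Archaea	14	1.77	500735.939096617
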