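meta_analysis,screened_original,included,citing_articles,screened_s1,retrieved_s1,screened_s12,retrieved_s12
Mehrabi,4148,29,170,1113,29,1383,29
Pathak,543,6,1437,584,6,886,6
Viswanathan,2749,6,74,627,6,689,6
Vrablik,7771,3,28,68,3,81,3
vanWely,894,18,106,444,18,615,18
Schuit,39,13,171,1221,12,1385,13
Deng,362,9,928,533,8,1726,9
Nwachuku,464,15,62,404,13,502,15
Gu2015,764,19,104,719,16,908,19
SanLorenzo,3529,19,67,296,15,468,19
Al-Wassia,166,7,8,32,4,52,7
Elshaer,750,30,35,210,21,235,29
Mumme,701,21,55,271,19,468,20
Hazlewood,1463,35,897,861,28,3162,33
Sheyin,221,17,40,180,16,392,16
Yuan,7175,14,51,490,10,596,13
Elmariah,1934,14,3870,599,5,836,13
Cheelo,1192,11,112,919,9,1017,10
Gu2015b,326,18,14,59,13,233,16
Saleh,1480,14,499,964,12,1055,12
Emdin,10598,45,3223,395,26,6116,36
Sayegh,594,22,69,529,14,759,17
Kamper,6189,41,968,857,28,1227,31
Taioli,98,24,85,441,16,595,18
Sharpe,3875,7,92,886,5,911,5
Zhang,468,7,221,140,5,198,5
Siddiqui,3119,13,129,824,8,1002,9
Mair-Jenkins,1449,32,75,971,22,1086,22
Bonitsis,795,52,117,937,30,1489,34
Williams,1976,19,21,95,10,186,12
Souto,4527,23,580,913,12,1372,14
Zhen,742,25,59,215,13,290,15
Shan,243,19,60,289,9,344,11
Marcuzzi,5009,15,85,739,7,851,8
Lipinski,824,17,420,531,6,610,9
Stevens,400,6,62,536,3,551,3
Bernstein,1837,53,98,376,19,505,22
Avni,5365,103,104,698,29,1259,39
Kumar,573,16,101,926,5,1013,5
Fazeli,1195,5,4,7,1,7,1
Brydges,11628,33,63,347,4,391,6
McNally,2453,88,45,374,6,399,9
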