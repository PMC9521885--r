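"unit_id","zip","poi_type","A","D","SS","SDS","n_complaint_intervals","n_baseline_intervals"
"B00001","Z001","grocery",43.5420191765369,0.547869674185464,0.897908301381031,95.0620833819975,15,48
"B00002","Z001","food_and_drink",29.2747837658017,0.615737704918033,0.902975462589785,95.0114208131411,15,48
"B00003","Z001","store",29.344512195122,0.2753125,0.404028498133458,100,10,53
"B00004","Z001","clinic",16.7214438101828,0.724324324324324,0.886046949674378,95.1806757304173,9,33
"B00005","Z001","food_and_drink",96.2728648053913,0.679741578218735,1.34827006824208,90.5592694623495,11,52
"B00006","Z002","food_and_drink",58.7983750267265,1.44158878504673,2.55069720761618,78.5371440091322,6,57
"B00007","Z002","store",32.5637196092354,1.85785123966942,2.81043474941976,75.9402321379494,11,52
"B00008","Z002","clinic",30.731102850062,0.952340425531915,1.4166808046728,89.875284188909,5,37
"B00009","Z002","store",15.6477880408362,1.75535019455253,2.09668322639989,83.0764735543204,8,55
"B00010","Z002","store",50.887573964497,2.55017793594306,4.35216362147681,60.5256949009032,5,58
"B00011","Z003","food_and_drink",30.3840544482256,1.10055096418733,1.63172718291161,87.7252041942136,2,61
"B00012","Z003","clinic",32.2703113135915,2.22784810126582,3.36138424424786,70.4317204549398,2,40
"B00013","Z003","grocery",82.9764453961456,3.27111111111111,6.27711445395242,41.2796219859629,1,62
"B00014","Z003","gym",45.2948789055278,2.35842696629213,3.90567086183625,64.9898256532631,2,61
"B00015","Z003","food_and_drink",42.5790754257908,0.879194630872483,1.43238057524926,89.7183145021177,3,60
"B00020","Z004","food_and_drink",138.794854434665,4.85714285714286,10.4058134907556,0,1,62
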