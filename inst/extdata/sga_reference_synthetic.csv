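"sex","week","p10_grams"
"female",24,522
"female",25,598
"female",26,684
"female",27,779
"female",28,884
"female",29,998
"female",30,1121
"female",31,1264
"female",32,1425
"female",33,1606
"female",34,1805
"female",35,2004
"female",36,2204
"female",37,2394
"female",38,2565
"female",39,2708
"female",40,2812
"female",41,2888
"female",42,2936
"male",24,550
"male",25,630
"male",26,720
"male",27,820
"male",28,930
"male",29,1050
"male",30,1180
"male",31,1330
"male",32,1500
"male",33,1690
"male",34,1900
"male",35,2110
"male",36,2320
"male",37,2520
"male",38,2700
"male",39,2850
"male",40,2960
"male",41,3040
"male",42,3090
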