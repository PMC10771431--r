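series,sex,value
naive_total,F,366787
naive_total,M,173160
algorithm_total,F,234475
algorithm_total,M,100924
official_total,F,254830
official_total,M,112824
algorithm_1998,All,16180
algorithm_2019,All,13929
gt2_fracture_persons,F,953
gt2_fracture_persons,M,353
algorithm_persons,F,207982
algorithm_persons,M,92036
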