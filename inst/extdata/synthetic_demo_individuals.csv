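individual_id,site,chamber_id,run_id,temp_level_c,dry_mass_mg,length_mm
ind0001,Quarantia,ch1,run0001,9,7.638659794526793,12.733649132379043
ind0002,Quarantia,ch2,run0002,9,1.239236285388362,6.948129981176718
ind0003,Quarantia,ch3,run0003,9,4.399158144751217,10.060273872448708
ind0004,Quarantia,ch4,run0004,18,0.6085071345946944,5.483259792726584
ind0005,Quarantia,ch5,run0005,18,9.603059120198008,13.306134011697651
ind0006,Quarantia,ch6,run0006,18,11.50298643720293,13.376615804383038
ind0007,Quarantia,ch1,run0007,25,0.6348395540952696,5.095147686786666
ind0008,Quarantia,ch2,run0008,25,1.1329651806743664,6.917010920391811
ind0009,Quarantia,ch3,run0009,25,0.47250563415596253,4.774622484803946
ind0010,Lesina,ch4,run0010,11,7.0847798486896245,12.01064927424731
ind0011,Lesina,ch5,run0011,11,0.4007473223497192,4.433745181213472
ind0012,Lesina,ch6,run0012,11,0.43091852601661523,4.8678300871127895
ind0013,Lesina,ch1,run0013,18,0.4840604973068685,5.041039527999504
ind0014,Lesina,ch2,run0014,18,12.042749729914688,15.443929911516022
ind0015,Lesina,ch3,run0015,18,0.432456479603561,4.6992931545966865
ind0016,Lesina,ch4,run0016,28,1.9409219793797226,8.016156131010261
ind0017,Lesina,ch5,run0017,28,1.730818974352555,7.00225265903423
ind0018,Lesina,ch6,run0018,28,1.0701164315509937,6.405959959363094
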