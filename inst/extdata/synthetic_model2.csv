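group,location,SLA,ARNODE,LOGCANH,LOGCAND
1,alpha,27.1534092656157,33.90894503815,1.51137755391833,1.15897451611077
1,gamma,25.5767688304125,40.7407881667031,1.6847619639225,1.38327172811968
1,alpha,25.6638061473122,38.3284318277185,1.73390552089217,1.51453200848737
1,gamma,32.8626387646902,29.553222906331,1.56435778610433,1.46494364104471
1,alpha,20.0211803113509,29.9086565508033,1.57087964670544,1.29068889495885
1,gamma,26.9783196142786,40.6924273675867,1.76543641991863,1.43082165443995
1,alpha,19.8698152266901,38.3223071317508,1.52365070446874,1.06716044073474
1,gamma,23.2215937742872,37.3797153846871,1.53596561017076,1.27442972380482
1,alpha,26.1783259226734,27.7823198794103,1.61155338977067,1.54301813184854
1,gamma,25.1869427283347,37.3453861094365,1.41345698286791,1.21229989626715
1,alpha,26.9884781736742,31.8015322527829,1.72581543079089,1.26893423121157
1,gamma,27.5097807112117,40.604073990218,1.23647571416451,1.58214831398296
1,alpha,26.3568293440403,33.7428341255136,1.72040753334679,1.44333663457397
1,gamma,27.3887743866183,26.8495935168785,1.42690334419625,1.38914084055204
1,alpha,27.2858904290193,33.6111813849996,1.91306684644391,1.45724554933125
1,gamma,25.2845813964238,31.7681401025988,1.57445951006774,1.33088953009744
1,alpha,28.210420605213,30.3696749006983,1.81079821158789,1.15363660188972
1,gamma,24.7288240392465,35.4020249806683,1.85092285229033,1.31033543300353
1,alpha,28.8385068366582,38.1268391418209,1.46891298380568,1.46856284891505
1,gamma,26.6275056135246,24.8952107284492,1.73842976072893,1.54435103605664
2,beta,21.7067001790764,23.0229361152015,1.45802308058629,1.36631161267418
2,delta,14.8432053666913,23.6051517703691,1.22896143738721,0.993996507220147
2,beta,15.5742183868857,29.7080641817797,1.24896123363874,1.53278246375575
2,delta,18.3960046086614,34.4589920655222,1.23549967544304,1.17925115182134
2,beta,17.2939072237453,22.5220000933851,1.10513919550109,1.34835506265084
2,delta,22.2279816543666,26.7021957526224,1.31046388911672,1.28796693738538
2,beta,16.1889117815561,18.2634471890592,1.45207449775836,1.10009569299378
2,delta,20.2028138778327,23.0032214128852,1.11069729729615,1.28822997808424
2,beta,22.8056857690487,22.6479862455662,1.45611454180112,1.25455554304307
2,delta,21.306518531764,29.0215331205115,1.02206969984467,1.05319109903581
2,beta,20.6426568949523,20.7327148785122,1.35788467142788,1.19265292144072
2,delta,24.253616859956,30.752439238721,1.53351609243535,0.875809765574718
2,beta,21.1650503975365,29.2182404367616,1.61855644008714,0.927599166161168
2,delta,14.9055754679496,24.6404667173684,1.62422852018701,1.19732412679523
2,beta,16.1206212026104,34.8005403262807,1.47191160413029,1.14915329794019
2,delta,19.229832860007,27.7999519299995,1.52699227583125,1.00742758897628
2,beta,16.9075738355576,27.1536616861036,1.36766136096996,1.16780788742985
2,delta,19.4957318695011,29.1093847442162,1.56548162533579,1.16419855695343
2,beta,19.838942246651,19.0558632240344,1.25955940289943,1.66850870443962
2,delta,18.4043490265109,24.7786172033078,1.29512656127132,1.18761417193691
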