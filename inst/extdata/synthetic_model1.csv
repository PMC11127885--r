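group,location,SLA,ARNODE,LOGCANH,LOGCAND,FLOWPER
1,alpha,20.9085933859077,37.2997931800612,1.61676080110585,1.36256201135888,5.31902636351716
1,alpha,18.1339858254329,35.4265726772764,1.72890819293941,1.46176373800363,5.39773998800041
1,alpha,21.615017253611,43.8769519836465,1.50706191467983,1.59322195149746,5.95163772297245
1,alpha,25.1477187318306,30.257771740868,1.40907925999462,1.29039017839566,4.64573086794146
1,alpha,24.2142543438369,33.941952108734,1.41990320354285,1.451308638143,5.50882225396117
1,alpha,29.6810565882802,39.4005276123526,1.72453956239083,1.39405665050334,5.35880332764581
1,alpha,26.0853645783246,36.4448808537086,1.46598864735774,1.18962732799038,4.95522953835856
1,alpha,26.9255761516431,37.1363044626129,1.51676103174437,1.56857684057367,5.06648255823876
1,alpha,26.8760662123455,37.881579711049,1.82636685961295,1.41829164411322,5.07861124375199
1,alpha,20.070187932235,35.9911951399329,1.4962769836993,1.42143543574536,4.67408882927823
1,alpha,25.7854562807751,32.5893573738224,1.73542462471263,1.48951231264166,3.58458800542386
1,alpha,28.7413457215114,37.3410508548314,1.76720019823884,1.48790262984494,4.26557141231557
1,alpha,23.8564844663793,34.9294786669188,1.38186257707969,1.2614809524025,4.40101039183928
1,alpha,23.6912402431239,34.414954863014,1.4912429750399,1.45674210557426,6.0099777890756
1,alpha,22.0128928340841,41.3074071231355,1.51612348771533,1.28880908033422,3.15475738650164
1,alpha,29.1295892702617,40.2205710127293,1.51821881508953,1.40705404717462,5.17712117464585
1,alpha,25.9650369936671,31.4112986116212,1.67521935652335,1.2850572663269,4.93424618355984
1,alpha,26.9231933165181,29.0529402505218,1.63961870439611,1.54105143318797,5.6370720465059
1,alpha,23.8689836331053,36.463061310684,1.50560384041851,1.40185967697703,5.00718436427336
1,alpha,25.9142790822745,33.9512822146965,1.856704328743,1.72262496768723,3.8799546625839
2,beta,19.8288450896378,16.2214945997042,1.37788031274322,1.11785234795065,4.25391468426884
2,beta,19.3177997014545,35.8728580968901,1.4276597152811,1.25343393314937,4.30246215951787
2,beta,18.0176088946018,24.3834412599455,1.38425495535298,1.32450940151425,5.13057068303188
2,beta,15.8166622704732,28.2700281141005,1.15881317281353,1.35014238379633,4.07279340755513
2,beta,25.6201402426318,34.5319531635094,1.27260287062706,1.17375565025167,4.16132181693282
2,beta,15.0375686013368,24.2705894668046,1.41124696182201,1.3306243225858,4.15668413490547
2,beta,14.2346615366158,20.1853337902469,1.22927829866289,1.00216030639353,4.27685438488332
2,beta,19.7949313543562,29.5380504835402,1.24373544375387,1.4084942168812,4.2825418596555
2,beta,20.7812703787618,20.2598959615313,1.13700744677475,0.973552601845611,3.70391507173869
2,beta,19.8744743135461,15.8957394452913,1.28338132052654,1.14240629005384,3.72242046672723
2,beta,19.7318820475142,24.6444695722212,1.54691370640806,1.5092401510066,3.46302828868643
2,beta,21.1209757074187,18.7936426114559,1.40703574390966,1.04155693229109,2.52174398188281
2,beta,20.9440371757199,28.6424272404449,1.45537833780644,1.16020070029457,3.74155704195701
2,beta,20.223306813163,21.7032166634152,1.59270757120051,1.22787801860128,4.03151875168466
2,beta,19.1823514654401,25.2496447949391,1.25740840913641,1.1233347917838,3.22672725041717
2,beta,23.9423157192712,24.9239422837266,1.57976113276179,1.3689607859763,4.64403772121622
2,beta,16.845345427157,29.7220918539751,1.52613979790644,1.17773837383908,4.4230446065104
2,beta,19.5009767058836,30.5269015925973,1.43796555075056,1.12898593800967,3.67717343759006
2,beta,19.4647807916914,26.3456452024204,1.35035935540537,1.24672003182164,4.40723388852628
2,beta,19.2415886169973,40.3622868470347,1.48404762646208,1.23312656861045,3.27990708933397
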