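species.codes,S001,S002,S003,S004,S005,S006,S007,S008,S009,S010,S011,S012
ranafum,0,10,0,0,0,0,0,9,0,0,6,7
nigipaf,0,6,0,3,0,0,0,0,0,0,7,0
vefigul,0,5,0,0,0,0,0,0,0,9,0,0
pufopim,10,0,3,0,6,0,0,0,7,0,10,0
fovopog,0,8,0,7,0,0,0,0,0,11,0,0
duculer,6,0,0,9,0,0,0,0,12,9,0,0
buvetoc,15,6,9,0,0,0,9,0,0,0,0,10
ruvodur,0,0,0,0,0,0,4,0,0,6,8,6
belomov,0,0,0,9,0,10,0,7,0,0,0,0
romanam,0,0,0,0,0,0,0,0,0,9,0,0
fudefif,11,0,0,0,0,0,0,10,9,0,0,11
varesot,0,10,0,0,0,0,0,0,0,5,0,8
mutelec,0,0,0,0,0,0,0,0,0,0,0,10
gifopum,8,0,0,0,0,0,7,0,0,0,5,0
dicifup,0,0,7,10,8,10,0,0,0,0,0,0
pilenig,8,0,10,0,0,0,0,0,5,0,8,0
rudalig,0,0,0,0,0,0,0,0,0,0,0,8
vavobef,8,0,7,0,11,0,0,0,7,0,13,0
rodunof,0,10,0,8,8,6,0,11,0,0,0,10
cumalun,0,0,0,0,0,0,5,0,0,0,0,0
novusab,14,0,0,0,0,0,0,0,5,0,13,0
fipelot,0,0,0,0,0,6,6,10,12,0,0,0
milicad,5,0,0,0,0,12,0,0,10,0,0,6
firotos,0,0,0,0,0,0,0,0,0,5,7,0
morosul,13,0,0,7,0,0,0,0,6,0,6,0
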