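species.codes,FLOWPER
ranafum,6
nigipaf,3
vefigul,2
pufopim,7
fovopog,2
duculer,7
buvetoc,8
ruvodur,2
belomov,2
romanam,4
fudefif,7
varesot,6
mutelec,3
gifopum,6
dicifup,4
pilenig,4
rudalig,3
vavobef,2
rodunof,2
cumalun,2
novusab,6
fipelot,5
milicad,2
firotos,3
morosul,6
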