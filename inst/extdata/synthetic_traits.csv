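# trait_db_version: synthetic-11
code,genus,epithet,SLA,ARNODE,LOGCANH,LOGCAND,VEGPROP,LIFEHIST,FLOWPER
ranafum,ranaa,fumudi, 15.70504771767987,20.898111955642452,1.1392813222668745,0.77527435951127555,                 1,perennial,                 6
nigipaf,nigium,pafofuis,32.151680086366262,23.106278793853196, 1.332998399713532,0.78744509041058475,                 0,perennial,                 3
vefigul,vefitumeis,guluboa,13.836324435849441,40.433633233093872, 1.398337422202903,1.3429359712886404,                 0,annual,                 2
pufopim,pufogi,pimabo,25.467200922781274,51.181067807863499,1.4326566088574573,1.3546576159347299,                 1,annual,                 7
fovopog,fovoum,pogusano,22.911819737721665,20.704610876742603,1.4838294081038601,1.1567663668822032,                 0,other,                 2
duculer,ducuum,leralua,22.693745562699309,31.061685152963271,1.0368775005647044,1.0245878520725402,                 0,perennial,                 7
buvetoc,buve,tocu,14.102983679137306,33.433745045366074,1.4714833291262652,1.5644353174663328,                 1,annual,                 8
ruvodur,ruvoveco,durasia,20.448273507254196, 26.04132908859664,1.0221279632404905,1.4018480120180945,                 0,annual,                 2
belomov,belotoa,movocevoum,17.791330651134437,23.467661364791578,1.4742990697919345,0.62117487640201341,                 0,perennial,                 2
romanam,romavoum,namoliis,18.274947398511245,23.594368905025167,1.1824993588324644,1.2389477246972787,                 0,perennial,                 4
fudefif,fudeum,fifubibiis,25.936742244252592,40.662014472098065,1.3281993425455043,0.95304239493041154,                 0,perennial,                 7
varesot,varetuum,sotapium,24.976446227176417,33.172747682328207,1.7324280873446225,0.35787753173331505,                 0,annual,                 6
mutelec,mutefebais,leculenu, 23.64066107363314,27.048358047352878,1.6358403946478477, 1.001710276736292,                 0,annual,                 3
gifopum,gifoum,pumogu,23.173604707601921,33.505085477587272,1.5358972969137035,1.1423238381589291,                 1,perennial,                 6
dicifup,dicisocuis,fupibopu,18.680502688014776,34.525817207328345,1.3695862905729559,1.3275205406429491,                 1,annual,                 4
pilenig,pilevavais,nigama,31.564094853317833,28.746484495542695,1.6488048740463948,1.4470520680430787,                 1,annual,                 4
rudalig,rudacu,ligofea,16.056658323589367,40.623739302785722,1.8008765988942677, 1.525476661865959,,perennial,                 3
vavobef,vavois,befo,22.243582529375033,42.540396294151648,1.9669435583973522, 1.491291055897682,,perennial,                 2
rodunof,rodugois,nofodolu, 25.61207513909816,37.060431601349777,  1.37202445842986,0.8450065879251607,                 0,perennial,                 2
cumalun,cumaum,lunureum,25.393362953278753,34.577919067877218,2.0866547828389974,1.7236903298751876,                 1,annual,                 2
novusab,novucosoa,sabais,15.188690565021684,33.180408165997662,1.8962812559195612, 2.019146818200956,                 1,perennial,                 6
fipelot,fipea,lotevuis, 24.44365011952457,35.452707032275249,1.7951843572753583,1.0410857167716796,                 0,annual,                 5
milicad,mili,cadulameis,23.879479428672187,16.773776159379626,1.6866159127766294,1.2982661569038549,,perennial,                 2
firotos,fironea,tosepabo,30.696105661194583,38.772615768029389,2.0349205348940718,1.6370248861361563,                 0,perennial,                 3
morosul,morora,suleis,21.185177020878754,39.901268129206173,1.5832164870726559,1.1138450569903808,                 1,perennial,                 6
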