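group,location,VEGPROP,FLOWPER
1,alpha,0.504769330822207,4.890642878564
1,gamma,0.557126591081285,4.58235744517934
1,alpha,0.664384894255159,4.00748349289872
1,gamma,0.616206373995588,4.71650373849524
1,alpha,0.479309827073144,5.18349438676024
1,gamma,0.760637710826746,5.55896390520768
1,alpha,0.427825113155397,6.1942405198549
1,gamma,0.679788666018963,3.89973496785505
1,alpha,0.69669189280324,5.67175732654391
1,gamma,0.660939369496746,5.02694939748654
1,alpha,0.223974380499434,5.67116997883633
1,gamma,0.353027515126118,3.5391198117037
1,alpha,0.634423498078667,5.84847154054982
1,gamma,0.505082464950644,4.75526663173174
1,alpha,0.553975924358909,5.92804421206413
1,gamma,0.591358698495986,6.51804621871612
1,alpha,0.676198407854159,4.92986814852674
1,gamma,0.554426046000797,6.62346098058885
1,alpha,0.471335788739069,6.33231843140726
1,gamma,0.584845576407862,4.89832921897499
2,beta,0.287315997432642,3.1571458992981
2,delta,0.287771238561825,3.48794180064694
2,beta,0.248535404886517,4.48373359927284
2,delta,0.338513200361618,3.35451515428531
2,beta,0.21263303760068,2.66491894530565
2,delta,0.530000217573878,3.02429535603143
2,beta,0.271303193268659,3.79235791979579
2,delta,0.256338900989165,3.09403738522141
2,beta,0.165763377358773,4.15467580941497
2,delta,0.623287179933488,3.955372509678
2,beta,0.186308432447559,2.71370737792927
2,delta,0.158361285094474,5.07443686752906
2,beta,0.123724469850537,4.25528842469507
2,delta,0.139759840896092,4.48852895040715
2,beta,0.315833614113923,3.86109705326164
2,delta,0.254958774144549,2.93464499781921
2,beta,0.123448712149466,3.79632138439022
2,delta,0.423282385991267,4.07609130777718
2,beta,0.234515832168355,3.54274198867337
2,delta,0.237575418522418,3.20784061417981
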