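region_id,name,hemisphere,network,x,y,z
1,pSTS_L,L,visual_sensory,-50,-52,10
2,pSTS_R,R,visual_sensory,50,-52,10
3,FG_L,L,visual_sensory,-42,-62,-16
4,FG_R,R,visual_sensory,42,-62,-16
5,MT-V5_L,L,visual_sensory,-46,-70,2
6,MT-V5_R,R,visual_sensory,46,-70,2
7,AM_L,L,limbic,-22,-4,-18
8,AM_R,R,limbic,22,-4,-18
9,HC_L,L,limbic,-26,-20,-14
10,HC_R,R,limbic,26,-20,-14
11,NAC_L,L,limbic,-10,10,-8
12,NAC_R,R,limbic,10,10,-8
13,vmPFC,midline,limbic,0,44,-14
14,rACC,midline,limbic,0,40,12
15,AI_L,L,intermediate,-38,6,2
16,AI_R,R,intermediate,38,6,2
17,aMCC,midline,intermediate,0,22,34
18,IFG_L,L,intermediate,-48,26,4
19,IFG_R,R,intermediate,48,26,4
20,SMA_L,L,intermediate,-6,10,60
21,SMA_R,R,intermediate,6,10,60
22,SMG_L,L,intermediate,-58,-40,34
23,SMG_R,R,intermediate,58,-40,34
24,Cereb_L,L,intermediate,-24,-76,-34
25,Cereb_R,R,intermediate,24,-76,-34
26,TP_L,L,higher_associative,-44,12,-32
27,TP_R,R,higher_associative,44,12,-32
28,dmPFC,midline,higher_associative,0,54,24
29,MTG_L,L,higher_associative,-58,-14,-16
30,MTG_R,R,higher_associative,58,-14,-16
31,pMCC,midline,higher_associative,0,-14,40
32,FP,midline,higher_associative,0,60,0
33,TPJ_L,L,higher_associative,-54,-58,28
34,TPJ_R,R,higher_associative,54,-58,28
35,PCC,midline,higher_associative,0,-50,28
36,Prec,midline,higher_associative,0,-60,40
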