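study_id,study_name,design,intervention,intervention_label,events,size,cluster_adjusted,quality
1,Kelly 1987,RCT,1,Usual care (UC),43,54,FALSE,A=U;B=Y;F=N
1,Kelly 1987,RCT,2,Education (E),49,55,FALSE,A=U;B=Y;F=N
2,Nansel 2002,RCT,1,Usual care (UC),65,89,FALSE,A=Y;B=U;F=Y
2,Nansel 2002,RCT,2,Education (E),66,85,FALSE,A=Y;B=U;F=Y
3,McDonald 2005,RCT,1,Usual care (UC),3,57,FALSE,A=Y;B=U;F=N
3,McDonald 2005,RCT,2,Education (E),6,61,FALSE,A=Y;B=U;F=N
4,Gielen 2007,RCT,1,Usual care (UC),44,62,FALSE,A=Y;B=N;F=Y
4,Gielen 2007,RCT,2,Education (E),57,73,FALSE,A=Y;B=N;F=Y
5,Nansel 2008,NRCT,1,Usual care (UC),59,73,FALSE,A=U;B=N;F=N
5,Nansel 2008,NRCT,2,Education (E),117,144,FALSE,A=U;B=N;F=N
6,Woolf 1992,clusterRCT,1,Usual care (UC),60,151,FALSE,A=U;B=Y;F=N
6,Woolf 1992,clusterRCT,3,Education + free/low cost equipment (E + FE),89,150,FALSE,A=U;B=Y;F=N
7,Clamp 1998,RCT,1,Usual care (UC),49,82,FALSE,A=U;B=N;F=Y
7,Clamp 1998,RCT,3,Education + free/low cost equipment (E + FE),59,83,FALSE,A=U;B=N;F=Y
8,Kendrick 1999,clusterNRCT,1,Usual care (UC),317,367,FALSE,B=N;F=N;C=Y
8,Kendrick 1999,clusterNRCT,4,Education + free/low cost equipment + fitting (E + FE + F),322,363,FALSE,B=N;F=N;C=Y
9,Swart 2008,NRCT,1,Usual care (UC),46.86,57.96,TRUE,A=U;B=Y;F=Y
9,Swart 2008,NRCT,4,Education + free/low cost equipment + fitting (E + FE + F),50.87,58.27,TRUE,A=U;B=Y;F=Y
10,Hendrickson 2002,RCT,1,Usual care (UC),14,40,FALSE,A=N;B=N;F=Y
10,Hendrickson 2002,RCT,4,Education + free/low cost equipment + fitting (E + FE + F),34,38,FALSE,A=N;B=N;F=Y
11,Watson 2005,clusterRCT,1,Usual care (UC),327,669,FALSE,A=Y;B=N;F=Y
11,Watson 2005,clusterRCT,5,Education + free/low cost equipment + home safety inspection (E + FE + HSI),368,693,FALSE,A=Y;B=N;F=Y
12,Posner 2004,RCT,2,Education (E),22,47,FALSE,A=Y;B=Y;F=N
12,Posner 2004,RCT,3,Education + free/low cost equipment (E + FE),34,49,FALSE,A=Y;B=Y;F=N
13,Sznajder 2003,RCT,2,Education (E),32,41,FALSE,A=Y;B=N;F=Y
13,Sznajder 2003,RCT,5,Education + free/low cost equipment + home safety inspection (E + FE + HSI),40,48,FALSE,A=Y;B=N;F=Y
14,Dershewitz 1977,RCT,3,Education + free/low cost equipment (E + FE),1,101,FALSE,A=U;B=Y;F=N
14,Dershewitz 1977,RCT,7,Free/low-cost equipment (FE only),0,104,FALSE,A=U;B=Y;F=N
15,King 2001,RCT,4,Education + free/low cost equipment + fitting (E + FE + F),261,469,FALSE,A=Y;B=Y;F=Y
15,King 2001,RCT,6,Education + free/low cost equipment + fitting + home safety inspection (E + FE + F + HSI),273,482,FALSE,A=Y;B=Y;F=Y
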