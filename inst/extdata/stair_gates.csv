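study_id,study_name,design,intervention,intervention_label,events,size,cluster_adjusted,quality
1,Nansel 2002,RCT,1,Usual care (UC),70,89,FALSE,A=U;B=Y;F=N
1,Nansel 2002,RCT,2,Education (E),76,85,FALSE,A=U;B=Y;F=N
2,Kendrick 2005,RCT,1,Usual care (UC),348.44,436.80,TRUE,A=Y;B=U;F=Y
2,Kendrick 2005,RCT,2,Education (E),310.93,376.78,TRUE,A=Y;B=U;F=Y
3,Nansel 2008,NRCT,1,Usual care (UC),29,38,FALSE,A=Y;B=U;F=N
3,Nansel 2008,NRCT,2,Education (E),60,69,FALSE,A=Y;B=U;F=N
4,Clamp 1998,RCT,1,Usual care (UC),50,69,FALSE,A=Y;B=N;F=Y
4,Clamp 1998,RCT,3,Education + free/low cost equipment (E + FE),52,64,FALSE,A=Y;B=N;F=Y
5,McDonald 2005,RCT,1,Usual care (UC),10,41,FALSE,A=U;B=N;F=N
5,McDonald 2005,RCT,3,Education + free/low cost equipment (E + FE),23,54,FALSE,A=U;B=N;F=N
6,Kendrick 1999,NRCT,1,Usual care (UC),214.26,323.61,TRUE,A=U;B=Y;F=N
6,Kendrick 1999,NRCT,4,Education + free/low cost equipment + home safety inspection (E + FE + HSI),223.15,323.61,TRUE,A=U;B=Y;F=N
7,Watson 2005,RCT,1,Usual care (UC),328,718,FALSE,A=U;B=N;F=Y
7,Watson 2005,RCT,5,Education + free/low cost equipment + fitting (E + FE + F),408,742,FALSE,A=U;B=N;F=Y
8,Phelan 2010,RCT,1,Usual care (UC),78,147,FALSE,B=N;F=N;C=Y
8,Phelan 2010,RCT,6,Education + free/low cost equipment + fitting + home safety inspection (E + FE + F + HSI),131,146,FALSE,B=N;F=N;C=Y
9,Posner 2004,RCT,2,Education (E),25,47,FALSE,A=U;B=Y;F=Y
9,Posner 2004,RCT,3,Education + free/low cost equipment (E + FE),28,49,FALSE,A=U;B=Y;F=Y
10,Sznajder 2003,RCT,2,Education (E),45,50,FALSE,A=N;B=N;F=Y
10,Sznajder 2003,RCT,5,Education + free/low cost equipment + fitting (E + FE + F),44,47,FALSE,A=N;B=N;F=Y
11,Gielen 2002,RCT,3,Education + free/low cost equipment (E + FE),12.85,47.44,TRUE,A=Y;B=N;F=Y
11,Gielen 2002,RCT,4,Education + free/low cost equipment + home safety inspection (E + FE + HSI),10.87,47.44,TRUE,A=Y;B=N;F=Y
12,King 2001,RCT,4,Education + free/low cost equipment + home safety inspection (E + FE + HSI),158,482,FALSE,A=Y;B=Y;F=N
12,King 2001,RCT,7,Education + home safety inspection (E + HSI),166,469,FALSE,A=Y;B=Y;F=N
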