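from	to	assignment
895	905	beta-glycosidic linkage (cellulose)
1020	1065	C-O / C-C stretch, polysaccharides (cellulose, hemicellulose)
1100	1120	C-OH skeletal vibration, cellulose
1150	1170	C-O-C asymmetric stretch, cellulose/hemicellulose
1225	1275	C-O stretch of guaiacyl ring (lignin) / acetyl C-O (xylan)
1315	1340	syringyl ring breathing with C-O stretch (lignin); CH2 wag (cellulose)
1360	1380	C-H deformation, polysaccharides
1420	1440	aromatic skeletal vibration + C-H in-plane deformation (lignin)
1450	1470	C-H deformation, asymmetric (lignin/polysaccharides)
1500	1520	aromatic skeletal vibration (lignin, G+S units)
1585	1615	aromatic skeletal vibration + C=O stretch (lignin)
1630	1665	absorbed water / conjugated C=O
1700	1745	unconjugated C=O stretch (xylan acetyl, ester)
2840	2870	symmetric C-H stretch, methyl/methylene
2900	2945	asymmetric C-H stretch, methyl/methylene
3200	3500	O-H stretch (hydroxyl, hydrogen-bonded)
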