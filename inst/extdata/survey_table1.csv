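sample_id,name,concentration_mg_ml,grid_type,t_center,t_edge,t_substrate,layers_center,layers_edge,layers_substrate,preferred_orientation,min_layer_distance,intentionally_thick,affinity,no_awi_interaction
1,32 kDa Kinase,,Carbon Spotiton,65,45,--,0,0,0,unknown,<5,FALSE,FALSE,unknown
2,32 kDa Kinase,,Gold Spotiton,30,--,--,0,--,--,unknown,<5,FALSE,FALSE,unknown
3,Insulin Receptor,,Gold Spotiton,55,--,--,1-2,--,--,no,5,FALSE,FALSE,unknown
4,Hemagglutinin,,Carbon Spotiton,25-95,100-210,--,0 or 2,2,--,some,5,FALSE,FALSE,unknown
5,HIV-1 Trimer Complex 1,,Carbon Spotiton,75-210,--,--,2,--,--,yes,5-10,FALSE,FALSE,unknown
6,HIV-1 Trimer Complex 1,,Gold Spotiton,20,--,--,1,--,--,some,5,FALSE,FALSE,unknown
7,HIV-1 Trimer Complex 2,,Carbon Spotiton,190,265,--,2,2,2,yes,5,FALSE,FALSE,unknown
8,147 kDa Kinase,,Gold Spotiton,15,--,--,1,--,--,unknown,<5,FALSE,FALSE,unknown
9,150 kDa Protein,,Holey Carbon Spotiton,35,70,--,2,2,2,some,<5,FALSE,FALSE,unknown
10,Stick-like Protein 1,,Carbon Spotiton,80,--,--,1,--,--,no,<5,TRUE,FALSE,unknown
11,Stick-like Protein 2 (150 kDa),,Carbon CFlat,100,100,--,1,1,--,unknown,5,TRUE,FALSE,unknown
12,Stick-like Protein 2,,Gold Spotiton,135-190,--,--,1,--,--,some,5,TRUE,FALSE,unknown
13,Neural Receptor,,Carbon Spotiton,60-90,--,--,1,--,--,yes,5,TRUE,FALSE,unknown
14,Neural Receptor,,Carbon Spotiton,80-90,100-140,135,1,1,1,yes,5,TRUE,FALSE,unknown
15,200 kDa Protein,,CFlat Carbon + Gold mesh,40-60,95,110,1,1,2,no,5,FALSE,FALSE,unknown
16,Small Popular Protein,,Carbon Spotiton,30,70,--,1,2,2,no,5,FALSE,FALSE,unknown
17,Glycoprotein with Bound Lipids (deglycosylated),,Carbon Spotiton,15,90,130,1,2,2,yes,<5,FALSE,FALSE,unknown
18,Glycoprotein with Bound Lipids (deglycosylated),,Gold Spotiton,155,--,--,2,--,--,some,<5,TRUE,FALSE,unknown
19,Lipo-protein,,Holey Carbon,0-95,85-100,--,uniform,--,--,unknown,5,FALSE,FALSE,unknown
20,GPCR,,Carbon Spotiton,25,--,--,1,2,--,no,5,FALSE,FALSE,unknown
21,Rabbit Muscle Aldolase (1 mg/mL),1,Gold Spotiton,15,50,--,1,2,--,no,<5,FALSE,FALSE,unknown
22,Rabbit Muscle Aldolase (6 mg/mL),6,Carbon Spotiton,60-110,75-130,85,2,2,2,some,5,FALSE,FALSE,unknown
23,Un-named Protein,,Holey Carbon,35,--,60,1,--,2,yes,5,FALSE,FALSE,unknown
25,Protein in Nanodisc (0.58 mg/mL),0.58,Gold Spotiton,30,65,--,1-2,2,--,no,5-10,FALSE,FALSE,yes
26,IDE,,Carbon Spotiton,25,60,95,1,2,2,unknown,5,FALSE,FALSE,unknown
27,IDE,,Gold Spotiton,40,--,--,1,--,--,no,5-10,FALSE,FALSE,unknown
28,Small Helical Protein,,Gold Spotiton,50,75,--,1,2,--,some,5,FALSE,FALSE,unknown
29,300 kDa Protein,,Carbon Spotiton,30,100,--,1,2,2,no,5,FALSE,FALSE,unknown
30,GDH,,Holey Carbon,30,85,100,1,1,3,some,5,FALSE,FALSE,unknown
31,GDH,,Holey Carbon,60,120,140,1,2,3,yes,5,FALSE,FALSE,unknown
32,GDH (2.5 mg/mL)+0.001% DDM,2.5,Carbon Spotiton,50,180,190,1,2,--,yes,<5,FALSE,FALSE,unknown
33,DnaB Helicase-helicase Loader,,Gold Quantifoil,50-55,80-100,--,1,2,--,no,5,FALSE,FALSE,unknown
34,Apoferritin,,Gold Spotiton,25-30,--,--,1,--,--,no,5,FALSE,FALSE,unknown
35,Apoferritin,,Gold Spotiton,25,--,--,1,--,--,no,5,FALSE,FALSE,unknown
36,Apoferritin,,Holey Carbon Spotiton,30,125,135,1,2,2,no,5,FALSE,FALSE,unknown
37,Apoferritin (1.25 mg/mL),1.25,Holey Carbon Spotiton,30-50,100,105,1,2,2,no,5,FALSE,FALSE,unknown
38,Apoferritin (0.5 mg/mL),0.5,Holey Gold Spotiton,25-30,55,--,1,2,--,no,<5,FALSE,FALSE,unknown
39,Apoferritin with 0.5 mM TCEP,,Carbon Spotiton,40-90,145-175,--,1-2,2,1,no,5,FALSE,FALSE,unknown
40,Protein with Carbon Over Holes,,Carbon Quantifoil,110,70-100,--,1,1,--,some,5-10,FALSE,TRUE,unknown
41,Protein and DNA Strands with Carbon Over Holes,,Carbon Quantifoil,60,--,--,1,--,--,some,5-10,FALSE,TRUE,unknown
42,T20S Proteasome,,Holey Carbon,35,115,120,1,2,3,some,<5,FALSE,FALSE,unknown
43,T20S Proteasome,,Holey Carbon,125,140-160,150,2,2,2,some,5,FALSE,FALSE,unknown
44,T20S Proteasome,,Gold Quantifoil,50-75,--,--,1,--,--,some,5,FALSE,FALSE,unknown
45,Mtb 20S Proteasome,,Carbon Spotiton,35,80,115,0,1,1,no,5-10,FALSE,FALSE,unknown
46,Protein on Streptavidin,,Holey Carbon,20-100,80-120,--,0-2,1-2,--,no,10,FALSE,TRUE,yes
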