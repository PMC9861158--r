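id,peptide,binding_energy,site_label
1,AALKKAL,1.52,
2,AGAKKAV,1.83,
3,AGVKKVA,-0.44,H1.5K168
4,AKAKKPA,0.41,
5,AKPKAAK,0.7,
6,AKPKKAT,0.48,
7,ALKKALA,0.44,
8,APKKGSK,0.03,
9,ARAKAKT,0.74,
10,ARTKQTA,-1.42,H3K5
11,ATPKKAK,2.09,
12,ATPKKSA,-1.3,H1.2K148
13,AVTKAQK,0.33,
14,DVEKNNS,1.62,
15,EGTKAVT,0.74,
16,EHAKRKT,2.55,
17,ELAKHAV,1.04,
18,ELNKLLG,0.56,
19,EPAKSAP,-0.07,
20,GAAKKPK,1.86,
21,GAAKRKA,1.15,
22,GEAKPKV,2.49,
23,GGTKPKK,2.4,
24,GGVKKPH,-1.66,H3K37
25,GGVKRIS,1.46,
26,GITKPAI,1.36,
27,GLGKGGA,1.09,
28,GRGKGGK,0.32,
29,GRGKQGG,1.3,
30,GSFKLNK,0.22,
31,HYNKRST,2.75,
32,IHAKRVT,2.36,
33,KAAKKAG,1.04,
34,KAAKPKA,1.41,
35,KAAKPKV,0.27,
36,KATKKAA,2.64,
37,KDGKKRK,0.06,
38,KPKKAAK,-0.46,H1.2K184
39,KSPKKAK,1.75,
40,KTPKKAK,2.1,
41,LATKAAR,0.39,
42,LGLKSLV,1.73,
43,LIRKLPF,2.63,
44,LITKAVA,0.19,
45,LLRKGNY,0.44,
46,PAEKAPV,-0.75,H1.2K17
47,PKAKKAG,0.14,
48,PVEKSPA,0.72,
49,QDFKTDL,1.9,
50,RDNKKTR,1.85,
51,RHRKVLR,2.88,
52,RSRKESY,1.95,
53,RYQKSTE,1.48,
54,SAAKAVK,0.85,
55,SHHKAKG,2.77,
56,SPAKPKA,1.04,
57,TGGKAPR,0.71,
58,TPRKASG,2.31,
59,TVTKKVA,-0.3,
60,VKPKAAK,-0.35,
61,VKPKKAA,1.08,
62,VQTKGTG,1.84,
63,YALKRQG,2.84,
64,YVYKVLK,3.44,
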