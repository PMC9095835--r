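"node_id","node_label","region","rsn"
1,"lh_bankssts","L_T","AUD"
2,"lh_caudalanteriorcingulate","L_L","SAN"
3,"lh_caudalmiddlefrontal","L_F","DAN"
4,"lh_cuneus","L_O","VIS"
5,"lh_entorhinal","L_L","Other"
6,"lh_fusiform","L_T","Other"
7,"lh_inferiorparietal","L_P","DMN"
8,"lh_inferiortemporal","L_T","Other"
9,"lh_isthmuscingulate","L_L","DMN"
10,"lh_lateraloccipital","L_O","VIS"
11,"lh_lateralorbitofrontal","L_PF","Other"
12,"lh_lingual","L_O","VIS"
13,"lh_medialorbitofrontal","L_PF","DMN"
14,"lh_middletemporal","L_T","DMN"
15,"lh_parahippocampal","L_L","DMN"
16,"lh_paracentral","L_C","Other"
17,"lh_parsopercularis","L_F","SAN"
18,"lh_parsorbitalis","L_PF","Other"
19,"lh_parstriangularis","L_F","Other"
20,"lh_pericalcarine","L_O","VIS"
21,"lh_postcentral","L_C","Other"
22,"lh_posteriorcingulate","L_L","DMN"
23,"lh_precentral","L_C","DAN"
24,"lh_precuneus","L_P","DMN"
25,"lh_rostralanteriorcingulate","L_L","DMN"
26,"lh_rostralmiddlefrontal","L_F","Other"
27,"lh_superiorfrontal","L_F","Other"
28,"lh_superiorparietal","L_P","DAN"
29,"lh_superiortemporal","L_T","AUD"
30,"lh_supramarginal","L_P","AUD"
31,"lh_frontalpole","L_PF","Other"
32,"lh_temporalpole","L_T","Other"
33,"lh_transversetemporal","L_T","AUD"
34,"lh_insula","L_L","SAN"
35,"rh_bankssts","R_T","AUD"
36,"rh_caudalanteriorcingulate","R_L","SAN"
37,"rh_caudalmiddlefrontal","R_F","DAN"
38,"rh_cuneus","R_O","VIS"
39,"rh_entorhinal","R_L","Other"
40,"rh_fusiform","R_T","Other"
41,"rh_inferiorparietal","R_P","DMN"
42,"rh_inferiortemporal","R_T","Other"
43,"rh_isthmuscingulate","R_L","DMN"
44,"rh_lateraloccipital","R_O","VIS"
45,"rh_lateralorbitofrontal","R_PF","Other"
46,"rh_lingual","R_O","VIS"
47,"rh_medialorbitofrontal","R_PF","DMN"
48,"rh_middletemporal","R_T","DMN"
49,"rh_parahippocampal","R_L","DMN"
50,"rh_paracentral","R_C","Other"
51,"rh_parsopercularis","R_F","SAN"
52,"rh_parsorbitalis","R_PF","Other"
53,"rh_parstriangularis","R_F","Other"
54,"rh_pericalcarine","R_O","VIS"
55,"rh_postcentral","R_C","Other"
56,"rh_posteriorcingulate","R_L","DMN"
57,"rh_precentral","R_C","DAN"
58,"rh_precuneus","R_P","DMN"
59,"rh_rostralanteriorcingulate","R_L","DMN"
60,"rh_rostralmiddlefrontal","R_F","Other"
61,"rh_superiorfrontal","R_F","Other"
62,"rh_superiorparietal","R_P","DAN"
63,"rh_superiortemporal","R_T","AUD"
64,"rh_supramarginal","R_P","AUD"
65,"rh_frontalpole","R_PF","Other"
66,"rh_temporalpole","R_T","Other"
67,"rh_transversetemporal","R_T","AUD"
68,"rh_insula","R_L","SAN"
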