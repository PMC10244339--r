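distance_km,dfe_nM,source_label,synthetic
0.5,573,riverine_bay_scotland,TRUE
0.8,210,riverine_bay_scotland,TRUE
1.5,95,urban_harbour,TRUE
2,48,urban_harbour,TRUE
3,22,kelp_forest_margin,TRUE
5,12,kelp_forest_margin,TRUE
8,6.5,continental_shelf,TRUE
12,3.1,continental_shelf,TRUE
18,1.8,continental_shelf,TRUE
25,0.9,shelf_break,TRUE
35,0.62,shelf_break,TRUE
45,0.41,shelf_break,TRUE
55,0.327,southern_ocean_transect,TRUE
70,0.28,southern_ocean_transect,TRUE
90,0.21,southern_ocean_transect,TRUE
120,0.15,southern_ocean_transect,TRUE
150,0.1,southern_ocean_transect,TRUE
180,0.07,southern_ocean_transect,TRUE
200,0.05,southern_ocean_transect,TRUE
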