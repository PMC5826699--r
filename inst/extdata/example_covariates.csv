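site,edge_distance,mature_forest
marsh_01,120.5,0.22
marsh_02,340.0,0.10
ridge_01,80.2,0.61
ridge_02,15.8,0.55
creek_01,210.7,0.44
creek_02,95.3,0.18
forest_01,430.1,0.83
forest_02,60.0,0.71
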