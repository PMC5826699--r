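site,occ_1,occ_2,occ_3,occ_4,occ_5
marsh_01,1,0,1,,0
marsh_02,0,0,0,0,0
ridge_01,0,1,,1,1
ridge_02,0,0,,,0
creek_01,1,1,1,0,1
creek_02,0,0,0,,0
forest_01,0,0,1,0,0
forest_02,,0,0,0,1
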