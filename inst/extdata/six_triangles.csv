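"shape_id","ring_id","x","y"
1,1,0.48925,0.548309
1,1,0.717741,0.264773
1,1,0.277972,0.204567
2,1,0.29125,0.430931
2,1,0.661082,0.465635
2,1,0.689741,0
3,1,0.417388,0.217412
3,1,0.405843,0.525097
3,1,0.849494,0.391994
4,1,0.690923,0.246812
4,1,0.349371,0.328199
4,1,0.584664,0.738397
5,1,0.674894,0.42175
5,1,0.443712,0.198965
5,1,0.19533,0.63112
6,1,1,0.793961
6,1,0.577558,0.274087
6,1,0,0.1343
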