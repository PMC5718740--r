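energy_mev,intensity
0.061486,0.06
0.063,0.103
0.065122,2.63
0.066831,4.53
0.071413,0.241
0.073363,0.163
0.075368,0.78
0.075749,1.51
0.077831,0.5
0.11043,0.0122
0.136343,0.199
0.17698,0.0043
0.201311,0.473
0.205794,3.34
0.28027,0.009
0.283267,0.266
0.295957,28.71
0.308455,29.7
0.316506,82.86
0.32917,0.0174
0.374485,0.726
0.416469,0.67
0.42052,0.069
0.468069,47.84
0.484575,3.189
0.48906,0.438
0.588581,4.522
0.59349,0.0421
0.59941,0.0039
0.604411,8.216
0.612462,5.34
0.70385,0.0053
0.7658,0.0013
0.884537,0.291
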