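image_id,hypertension,z,phi_sr,phi_std,phi_max,p_s
1,No,14,20.4,12.7,8,8.9
2,No,14,16.7,12.1,7,7.0
3,No,16,22.1,16.7,11,9.1
4,No,11,16.1,8.4,13,6.6
5,No,13,18.5,14.2,3,7.8
6,Yes,35,31.1,23.7,25,20.7
7,Yes,38,43.0,25.5,21,35.6
8,Yes,39,40.2,25.2,27,38.9
9,Yes,38,32.2,24.2,1,17.5
10,No,24,30.2,26.6,3,19.9
11,No,4,19.0,20.9,1,3.3
12,No,8,41.4,26.0,16,5.2
13,No,14,32.4,25.7,1,9.3
14,No,17,30.8,25.5,5,9.1
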