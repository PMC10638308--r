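{"universe_size":15,"gamma":0.5,"bias":-0.42104826122522354,"support_vectors":[[1,2,3,4,6,8,9,10,11,13,14],[0,2,4,6,10,12,14],[1,2,3,4,6,9,11,13],[0,1,10,11,12,13,14],[0,6,7,8,9,10,14]],"dual_weights":[-1.1786726160906256,-0.9425100289750844,0.93215330315288147,1.2848727418342605,1.8720413496252148],"platt_A":-0.73708887514658272,"platt_B":0.26214273110963404}
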