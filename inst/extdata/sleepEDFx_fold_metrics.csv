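experiment,fold,accuracy,f1,precision,recall,kappa
default,1,0.845,0.844,0.846,0.845,0.806
default,2,0.848,0.847,0.848,0.848,0.810
default,3,0.834,0.832,0.832,0.834,0.792
default,4,0.857,0.856,0.857,0.857,0.821
default,5,0.849,0.849,0.850,0.849,0.811
default,6,0.843,0.843,0.843,0.843,0.803
default,7,0.856,0.856,0.857,0.856,0.820
default,8,0.847,0.846,0.847,0.847,0.808
default,9,0.836,0.836,0.836,0.836,0.795
default,10,0.834,0.834,0.835,0.834,0.792
pso,1,0.957,0.956,0.957,0.957,0.946
pso,2,0.959,0.959,0.959,0.959,0.949
pso,3,0.963,0.963,0.963,0.963,0.954
pso,4,0.951,0.951,0.951,0.951,0.939
pso,5,0.945,0.945,0.946,0.945,0.932
pso,6,0.952,0.952,0.952,0.952,0.940
pso,7,0.964,0.964,0.964,0.964,0.955
pso,8,0.944,0.943,0.944,0.944,0.930
pso,9,0.945,0.945,0.946,0.945,0.932
pso,10,0.961,0.961,0.961,0.961,0.951
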