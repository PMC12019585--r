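compartment,GL_2010s,GL_2050s,BS_2010s
Birds,5.048656e-03,1.490990e-02,1.237110e-02
Pinnipeds,1.062421e-02,7.754153e-02,7.148973e-02
Maritime mammals,1.417246e-02,4.774963e-03,2.516999e-03
Migratory fish,6.195191e-02,6.233540e-02,6.320373e-02
Ice algae,6.258407e-02,5.316104e-02,6.388779e-02
Cetaceans,8.885116e-02,3.137842e-01,4.532786e-01
Demersal fish larvae,9.627418e-02,2.675364e-01,7.227460e-01
Planktivorous fish larvae,9.637280e-02,4.328851e-01,2.331033e-01
Snow ammonia,2.248572e-01,8.568849e-02,8.928734e-02
Snow nitrate,3.265977e-01,1.245446e-01,7.936141e-02
Ice ammonia,4.754215e-01,5.340487e-02,9.325340e-02
Benthos carn/scav feeders larvae,5.484466e-01,6.846217e-01,7.100788e-01
Benthos susp/dep feeders larvae,5.790206e-01,9.411860e-01,1.043274e+00
Ice nitrate,7.150457e-01,2.891845e-01,1.922444e-02
Ice detritus,7.873267e-01,8.152309e-01,1.119108e+00
Sediment porewater nitrate,9.893880e-01,7.307051e-01,9.118393e-01
Deep layer phytoplankton,1.092862e+00,1.398580e+00,9.070223e-01
Demersal fish,1.338207e+00,3.648652e+00,7.296833e+00
Planktivorous fish,1.387123e+00,6.343029e+00,3.368735e+00
Sediment porewater ammonia,1.584903e+00,2.063427e+00,2.510188e+00
Corpses,1.955949e+00,2.898967e+00,3.027624e+00
Carnivorous zooplankton,4.978142e+00,5.792072e+00,9.320204e+00
Surface layer phytoplankton,6.170512e+00,7.422738e+00,7.392445e+00
Deep layer detritus,6.348369e+00,6.665317e+00,8.912465e+00
Benthos carn/scav feeders,9.294691e+00,1.036397e+01,8.751406e+00
Surface layer detritus,1.061713e+01,1.126787e+01,1.137937e+01
Benthos susp/dep feeders,4.253288e+01,5.231259e+01,5.142915e+01
Omnivorous zooplankton,4.822393e+01,5.846732e+01,9.471605e+01
Macrophyte nitrogen,4.873217e+01,4.722330e+01,5.041410e+01
Surface layer ammonia,5.800559e+01,5.609282e+01,1.930920e+02
Deep layer ammonia,7.257979e+01,7.652691e+01,3.893234e+02
Surface layer nitrate,6.658904e+02,4.441402e+02,2.946609e+02
Deep layer nitrate,1.436946e+03,1.216641e+03,1.151911e+03
Sediment refractory detritus,1.592244e+04,1.592244e+04,1.766065e+04
Sediment labile plus refractory detritus,1.599796e+04,1.602212e+04,1.776644e+04
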