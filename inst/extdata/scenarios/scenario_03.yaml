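rho: 0.9182992324582302
delta1: 0.11722697035875172
delta2: 0.11235054582357408
b: 2.75654670735821128
b_G: 1.48152991943061352
l1: 1.47572458814829588
l2: 0.59200440091080964
c_I: 2.41745266114594415
c_M: 2.35886414255946875
c_F: 2.46847057295963168
c_H: 1.62984906230121851
c_G: 1.57378917699679732
alpha1: 0.26492848561611027
lambda1: 0.78788434341549873
lambda2: 1.18464964570011944
lambda3: 1.83461208897642791
lambda4: 1.22488868609070778
lambda_H: 0.3419660625513643
lambda_G: 0.31760870309080924
beta: 5.09231229860219159
beta_H: 27.55260761496610655
beta_G: 13.27841783810989007
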