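rho: 0.91031839726492769
delta1: 0.09813012989470736
delta2: 0.15205449922941627
b: 4.64177905849646777
b_G: 1.1855138223618269
l1: 1.55213045934215188
l2: 1.12356649036519229
c_I: 1.43222053768113256
c_M: 3.62976421089842916
c_F: 1.35714469663798809
c_H: 1.85282427619677037
c_G: 1.92966189922299236
alpha1: 0.77766479749698192
lambda1: 1.27367821952793747
lambda2: 1.17418468417599797
lambda3: 3.52669515856541693
lambda4: 1.33093324140645564
lambda_H: 0.53844684278592458
lambda_G: 0.20898113219300285
beta: 3.29155925733619359
beta_H: 16.38495455502998155
beta_G: 5.1501933597133025
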