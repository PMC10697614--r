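rho: 0.82423971407115459
delta1: 0.17749977251514792
delta2: 0.16960236845770854
b: 2.81538225815165788
b_G: 1.42287076264619827
l1: 1.72337488445919007
l2: 0.50079447310417891
c_I: 0.79753557551885024
c_M: 2.32338305399753153
c_F: 1.87086917902342975
c_H: 0.76430210296530277
c_G: 1.96006917173508555
alpha1: 0.75637203984661028
lambda1: 1.52143212629016489
lambda2: 0.581187758827582
lambda3: 3.89835965912789106
lambda4: 1.06641354667954147
lambda_H: 0.44131536997156218
lambda_G: 0.54278339106822382
beta: 6.51124373037484538
beta_H: 41.20829251618124545
beta_G: 8.38781389123178123
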