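host_id,phage_id,r,phi,tau,n_e,beta
CBA38,phi38:1,0.16503504299046315,2e-8,1.2,99,30
CBA18,phi38:1,0.11950813457930091,5e-8,1.5,99,20
CBA18,phi18:2,0.11950813457930091,1e-7,1,99,50
CBA4,phi18:3,0.13862943611198905,4e-8,0.9,99,45
CBA18,phi18:3,0.11950813457930091,8e-8,1.1,99,60
PSAH100,PSA-HP1,0.1925408834888737,2e-7,0.8,99,80
PSA1315,PSA-HP1,0.182407152778933,1e-7,1,99,50
PSAH100,PSA-HS6,0.1925408834888737,6e-8,1.3,99,25
PSA1315,PSA-HS6,0.182407152778933,1.5e-7,0.7,99,40
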