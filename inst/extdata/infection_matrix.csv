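host_id,phi38:1,phi18:2,phi18:3,PSA-HP1,PSA-HS6
CBA38,1,0,0,0,0
CBA4,0,0,1,0,0
CBA18,1,1,1,0,0
PSAH100,0,0,0,1,1
PSA1315,0,0,0,1,1
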