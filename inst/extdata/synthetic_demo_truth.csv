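individual_id,latent_smr,smr_j_per_day
ind0001,1.6446516296920697,1.8225438942352643
ind0002,0.31854546290421487,0.23402006459772176
ind0003,0.999485421333155,0.9832141667923832
ind0004,0.3421315450234204,0.27567599663823755
ind0005,2.708950470308423,2.5799268185831874
ind0006,3.101714486854654,2.875316875386135
ind0007,0.5942382801662212,0.7118859669802584
ind0008,0.8597601897522065,0.7977590954409444
ind0009,0.49223253665541034,0.5218554128147409
ind0010,1.2927213110038276,1.359815897439078
ind0011,0.10688828619214201,0.09932477160941161
ind0012,0.11383817721150853,0.10449740961287451
ind0013,0.2244372683278993,0.23933179418507275
ind0014,2.5001409180770833,2.193454771179279
ind0015,0.20624197014603993,0.20609689861639865
ind0016,1.1115783253101796,1.197321755930131
ind0017,1.0387837022737212,1.3965058753565012
ind0018,0.7817624830212665,0.6532903337261596
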