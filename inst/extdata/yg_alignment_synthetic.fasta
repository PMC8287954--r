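>hs/252-294 synthetic YG-box fragment, human SMN numbering
EMALIVEALISMALSWYMSGYHTGYYMGFRENMEMLACSQLEN
>dm/186-220 synthetic YG-box fragment, fruit-fly SMN numbering
---LIVEALIAMALSWYMSGYYTGLYQGKRENMEMLAC-----
>sp/116-152 synthetic YG-box fragment, fission-yeast SMN numbering
EMALIVEALISMALSWYMAGYYTGLAEGLAESMEMLA------
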