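raw,canonical
STELARA,ustekinumab
USTEKINUMAB,ustekinumab
ustekinumab.,ustekinumab
STELARA (USTEKINUMAB),ustekinumab
HUMIRA,adalimumab
ADALIMUMAB,adalimumab
REMICADE,infliximab
INFLIXIMAB,infliximab
ENTYVIO,vedolizumab
VEDOLIZUMAB,vedolizumab
XELJANZ,tofacitinib
TOFACITINIB,tofacitinib
METHOTREXATE,methotrexate
AZATHIOPRINE,azathioprine
IMURAN,azathioprine
PREDNISONE,prednisone
MESALAZINE,mesalazine
MESALAMINE,mesalazine
COSENTYX,secukinumab
SECUKINUMAB,secukinumab
ENBREL,etanercept
ETANERCEPT,etanercept
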