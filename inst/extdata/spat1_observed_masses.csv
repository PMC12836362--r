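fragment,enzyme,sequence,n_cam,observed_mh
native_cyclic,none,GIPCGESCVYIPCFTSVIGCSCSNKVCYKN,0,3150.1
gluc_full,endoGluC,SCVYJPCFTSVJGCSCSNKVCYKNGJPCGE,6,3516.19
tryp_26mer,trypsin,NGJPCGESCVYJPCFTSVJGCSCSNK,5,2966.3
tryp_vcyk,trypsin,VCYK,1,569.27
chym_18mer,chymotrypsin,JPCFTSVJGCSCSNKVCY,4,2151.73
chym_12mer,chymotrypsin,KNGJPCGESCVY,2,1383.60
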