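>gluc_full topology=linear enzyme=endoGluC
SCVYJPCFTSVJGCSCSNKVCYKNGJPCGE
>tryp_26mer topology=cyclic enzyme=trypsin
NGJPCGESCVYJPCFTSVJGCSCSNK
>tryp_vcyk topology=cyclic enzyme=trypsin
VCYK
>chym_18mer topology=cyclic enzyme=chymotrypsin
JPCFTSVJGCSCSNKVCY
>chym_12mer topology=cyclic enzyme=chymotrypsin
KNGJPCGESCVY
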