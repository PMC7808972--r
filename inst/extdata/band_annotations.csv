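wavenumber,assignment
760,"Tryptophan ring breathing"
1004,"Phenylalanine (collagen)"
1100,"C-C / C-O stretching"
1250,"Amide III"
1334,"CH3CH2 wagging (collagen)"
1342,"CH deformation (proteins and carbohydrates)"
1448,"CH2 deformation (collagen)"
1657,"Amide I (collagen)"
1660,"Amide I (proteins)"
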