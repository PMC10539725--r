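##TITLE= tiny synthetic SQZ/DIF/DUP decoding example
##JCAMP-DX= 4.24
##DATA TYPE= NMR SPECTRUM
##ORIGIN= jdeconv
##OWNER= jdeconv
##XUNITS= HZ
##YUNITS= ARBITRARY UNITS
##FIRSTX= 0
##LASTX= 11
##NPOINTS= 12
##XFACTOR= 1
##YFACTOR= 0.5
##XYDATA= (X++(Y..Y))
0 @ J K L % l k j
8 @ E U B
##END=
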