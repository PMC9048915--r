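"wavelength_nm","relative_flux"
300,0.339488
310,0.361126
320,0.386916
330,0.41713
340,0.45182
350,0.490739
360,0.53329
370,0.578513
380,0.625157
390,0.671801
400,0.717025
410,0.759575
420,0.798495
430,0.833184
440,0.863398
450,0.889188
460,0.910827
470,0.928721
480,0.943344
490,0.955175
500,0.964673
510,0.972249
520,0.978262
530,0.983014
540,0.986759
550,0.989701
560,0.992009
570,0.993817
580,0.995231
590,0.996335
600,0.997198
610,0.997871
620,0.998397
630,0.998806
640,0.999125
650,0.999374
660,0.999568
670,0.999719
680,0.999837
690,0.999929
700,1
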