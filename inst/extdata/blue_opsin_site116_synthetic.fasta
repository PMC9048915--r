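>squid_rhodopsin
--TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGSGYRCLNKACC
>Dryas_iulia
MQTFALEVTCHEFQYVRDKEFPFYCIDALMRIEEVPFECCDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGSGYRCLNKACC
>Eueides_isabella
LFTFALEVTRHLFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGSGYRCLNKACC
>Heliconius_erato
TFTFALEVTRHEFQYVRDKDFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGSGYRCLNKACC
>Heliconius_melpomene
QQTFALEVTRHEFQYVRDKEFPFYAIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGSGYRCLNKACC
>Heliconius_hecale
FDTFALEVTRHEFQYVRDKEFPFYCIDALMPIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGSGYRCLNKACC
>Heliconius_ismenius
MYTFALEVTRHEFQYVRDKEFPFYCIDALMRITEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGAGYRCLNKACC
>Heliconius_numata
YETFALEVTRHEFQYVRDKEFPFYCIDALMRIEEYPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGAGYRCLNKACC
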