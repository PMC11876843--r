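>SYN0001 HES5
A  [ 3 91 3 3 3 3 3 3 3 3 3 91 91 ]
C  [ 91 3 91 3 91 3 3 3 3 91 91 3 3 ]
G  [ 3 3 3 91 3 91 3 91 3 3 3 3 3 ]
T  [ 3 3 3 3 3 3 91 3 91 3 3 3 3 ]
>SYN0002 FOXP2
A  [ 3 3 3 3 3 91 3 3 3 3 3 3 91 3 ]
C  [ 3 3 3 3 3 3 91 3 3 3 3 91 3 91 ]
G  [ 3 91 3 3 3 3 3 3 3 3 91 3 3 3 ]
T  [ 91 3 91 91 91 3 3 91 91 91 3 3 3 3 ]
>SYN0003 GATA3
A  [ 91 3 91 3 91 91 3 91 3 3 3 3 3 ]
C  [ 3 3 3 3 3 3 3 3 3 91 3 3 3 ]
G  [ 3 91 3 3 3 3 91 3 91 3 91 3 3 ]
T  [ 3 3 3 91 3 3 3 3 3 3 3 91 91 ]
>SYN0004 PAX6
A  [ 3 3 3 91 3 3 3 91 3 3 91 3 3 3 ]
C  [ 3 3 91 3 91 3 91 3 3 3 3 3 3 3 ]
G  [ 3 3 3 3 3 91 3 3 3 91 3 91 3 91 ]
T  [ 91 91 3 3 3 3 3 3 91 3 3 3 91 3 ]
>SYN0005 SOX2
A  [ 3 3 3 3 3 3 3 3 3 3 3 91 3 91 ]
C  [ 91 91 3 3 3 3 3 3 91 3 3 3 91 3 ]
G  [ 3 3 3 3 3 91 3 3 3 3 91 3 3 3 ]
T  [ 3 3 91 91 91 3 91 91 3 91 3 3 3 3 ]
>SYN0006 OTX2
A  [ 3 3 91 3 3 91 3 3 3 3 3 3 3 ]
C  [ 3 3 3 3 3 3 3 91 3 3 91 91 3 ]
G  [ 91 91 3 3 3 3 91 3 3 91 3 3 3 ]
T  [ 3 3 3 91 91 3 3 3 91 3 3 3 91 ]
>SYN0007 EMX2
A  [ 3 91 91 3 3 91 3 3 3 3 3 3 91 ]
C  [ 3 3 3 3 3 3 91 91 3 3 3 91 3 ]
G  [ 3 3 3 3 3 3 3 3 91 91 3 3 3 ]
T  [ 91 3 3 91 91 3 3 3 3 3 91 3 3 ]
>SYN0008 DLX2
A  [ 3 3 91 91 3 3 3 3 3 91 3 3 3 ]
C  [ 91 3 3 3 3 3 3 3 91 3 91 3 3 ]
G  [ 3 3 3 3 3 3 91 91 3 3 3 3 91 ]
T  [ 3 91 3 3 91 91 3 3 3 3 3 91 3 ]
>SYN0009 LHX2
A  [ 3 3 91 91 3 3 91 3 3 3 3 91 3 ]
C  [ 3 3 3 3 3 3 3 3 91 3 3 3 3 ]
G  [ 3 3 3 3 3 3 3 91 3 91 91 3 3 ]
T  [ 91 91 3 3 91 91 3 3 3 3 3 3 91 ]
>SYN0010 NKX2-1
A  [ 3 3 91 3 3 3 91 91 3 3 3 3 3 ]
C  [ 91 91 3 91 3 91 3 3 3 3 3 3 3 ]
G  [ 3 3 3 3 3 3 3 3 91 3 91 91 3 ]
T  [ 3 3 3 3 91 3 3 3 3 91 3 3 91 ]
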