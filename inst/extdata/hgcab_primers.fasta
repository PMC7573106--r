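>ORNL-HgcAB-uni-F
AAYGTCTGGTGYGCNGCVGG
>ORNL-HgcAB-uni-R
CABGCNCCRCAYTCCATRCA
>ORNL-HgcAB-uni-32R
CAGGCNCCGCAYTCSATRCA
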