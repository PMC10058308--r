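res,atom,role
G,N1,donor
G,N2,donor
G,O6,acceptor
G,N3,acceptor
G,N7,acceptor
A,N6,donor
A,N1,acceptor
A,N3,acceptor
A,N7,acceptor
C,N4,donor
C,O2,acceptor
C,N3,acceptor
U,N3,donor
U,O2,acceptor
U,O4,acceptor
NUC,O2',both
NUC,O3',acceptor
NUC,O4',acceptor
NUC,O5',acceptor
NUC,OP1,acceptor
NUC,OP2,acceptor
NUC,OP3,acceptor
AA,N,donor
AA,O,acceptor
AA,OXT,acceptor
ARG,NE,donor
ARG,NH1,donor
ARG,NH2,donor
LYS,NZ,donor
HIS,ND1,both
HIS,NE2,both
ASN,ND2,donor
ASN,OD1,acceptor
GLN,NE2,donor
GLN,OE1,acceptor
SER,OG,both
THR,OG1,both
TYR,OH,both
TRP,NE1,donor
CYS,SG,both
ASP,OD1,acceptor
ASP,OD2,acceptor
GLU,OE1,acceptor
GLU,OE2,acceptor
MET,SD,acceptor
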