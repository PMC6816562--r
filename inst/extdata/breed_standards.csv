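breed,registry,trait,tolerance
BULT,AKC,brown,N
BULT,UKC,brown,N
BULT,KC,brown,N
BULT,FCI,brown,N
SKIP,AKC,red,N
SKIP,UKC,red,N
SKIP,KC,red,Y
SKIP,FCI,red,N
DANE,AKC,white_spotting,amb.
DANE,UKC,white_spotting,amb.
DANE,KC,white_spotting,amb.
DANE,FCI,white_spotting,amb.
DANE,AKC,harlequin,amb.
DANE,UKC,harlequin,amb.
DANE,KC,harlequin,amb.
DANE,FCI,harlequin,amb.
SSHP,AKC,white_spotting,N
SSHP,UKC,white_spotting,Y
SSHP,KC,white_spotting,n.p.
SSHP,FCI,white_spotting,n.p.
BLRT,AKC,brown,N
BLRT,UKC,brown,N
BLRT,KC,brown,N
BLRT,FCI,brown,N
BLRT,AKC,red,N
BLRT,UKC,red,N
BLRT,KC,red,N
BLRT,FCI,red,N
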