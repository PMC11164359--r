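synonym,canonical,kind
COX1,cox1,PCG
COI,cox1,PCG
CO1,cox1,PCG
COX-1,cox1,PCG
CYTOCHROME C OXIDASE SUBUNIT 1,cox1,PCG
CYTOCHROME C OXIDASE SUBUNIT I,cox1,PCG
COX2,cox2,PCG
COII,cox2,PCG
CO2,cox2,PCG
CYTOCHROME C OXIDASE SUBUNIT 2,cox2,PCG
CYTOCHROME C OXIDASE SUBUNIT II,cox2,PCG
COX3,cox3,PCG
COIII,cox3,PCG
CO3,cox3,PCG
CYTOCHROME C OXIDASE SUBUNIT 3,cox3,PCG
CYTOCHROME C OXIDASE SUBUNIT III,cox3,PCG
COB,cob,PCG
CYTB,cob,PCG
CYT B,cob,PCG
CYTOCHROME B,cob,PCG
ND1,nad1,PCG
NAD1,nad1,PCG
NADH DEHYDROGENASE SUBUNIT 1,nad1,PCG
ND2,nad2,PCG
NAD2,nad2,PCG
NADH DEHYDROGENASE SUBUNIT 2,nad2,PCG
ND3,nad3,PCG
NAD3,nad3,PCG
NADH DEHYDROGENASE SUBUNIT 3,nad3,PCG
ND4,nad4,PCG
NAD4,nad4,PCG
NADH DEHYDROGENASE SUBUNIT 4,nad4,PCG
ND4L,nad4L,PCG
NAD4L,nad4L,PCG
NADH DEHYDROGENASE SUBUNIT 4L,nad4L,PCG
ND5,nad5,PCG
NAD5,nad5,PCG
NADH DEHYDROGENASE SUBUNIT 5,nad5,PCG
ND6,nad6,PCG
NAD6,nad6,PCG
NADH DEHYDROGENASE SUBUNIT 6,nad6,PCG
ATP6,atp6,PCG
ATPASE6,atp6,PCG
ATP SYNTHASE F0 SUBUNIT 6,atp6,PCG
ATP8,atp8,PCG
ATPASE8,atp8,PCG
ATP SYNTHASE F0 SUBUNIT 8,atp8,PCG
ATPASE SUBUNIT 6,atp6,PCG
ATPASE SUBUNIT 8,atp8,PCG
RRNL,rrnL,rRNA
16S,rrnL,rRNA
16S RIBOSOMAL RNA,rrnL,rRNA
L-RRNA,rrnL,rRNA
LARGE SUBUNIT RIBOSOMAL RNA,rrnL,rRNA
RRNS,rrnS,rRNA
12S,rrnS,rRNA
12S RIBOSOMAL RNA,rrnS,rRNA
S-RRNA,rrnS,rRNA
SMALL SUBUNIT RIBOSOMAL RNA,rrnS,rRNA
TRNA,trnA,tRNA
TRNA-ALA,trnA,tRNA
TRNR,trnR,tRNA
TRNA-ARG,trnR,tRNA
TRNN,trnN,tRNA
TRNA-ASN,trnN,tRNA
TRND,trnD,tRNA
TRNA-ASP,trnD,tRNA
TRNC,trnC,tRNA
TRNA-CYS,trnC,tRNA
TRNE,trnE,tRNA
TRNA-GLU,trnE,tRNA
TRNQ,trnQ,tRNA
TRNA-GLN,trnQ,tRNA
TRNG,trnG,tRNA
TRNA-GLY,trnG,tRNA
TRNH,trnH,tRNA
TRNA-HIS,trnH,tRNA
TRNI,trnI,tRNA
TRNA-ILE,trnI,tRNA
TRNK,trnK,tRNA
TRNA-LYS,trnK,tRNA
TRNM,trnM,tRNA
TRNA-MET,trnM,tRNA
TRNF,trnF,tRNA
TRNA-PHE,trnF,tRNA
TRNP,trnP,tRNA
TRNA-PRO,trnP,tRNA
TRNT,trnT,tRNA
TRNA-THR,trnT,tRNA
TRNW,trnW,tRNA
TRNA-TRP,trnW,tRNA
TRNY,trnY,tRNA
TRNA-TYR,trnY,tRNA
TRNV,trnV,tRNA
TRNA-VAL,trnV,tRNA
TRNL1,trnL1,tRNA
TRNA-LEU(CUN),trnL1,tRNA
TRNA-LEU (CUN),trnL1,tRNA
TRNL2,trnL2,tRNA
TRNA-LEU(UUR),trnL2,tRNA
TRNA-LEU (UUR),trnL2,tRNA
TRNS1,trnS1,tRNA
TRNA-SER(AGN),trnS1,tRNA
TRNA-SER (AGN),trnS1,tRNA
TRNS2,trnS2,tRNA
TRNA-SER(UCN),trnS2,tRNA
TRNA-SER (UCN),trnS2,tRNA
CR,CR,CR
D-LOOP,CR,CR
CONTROL REGION,CR,CR
A+T RICH REGION,CR,CR
AT-RICH REGION,CR,CR
PUTATIVE CONTROL REGION,CR,CR
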