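# Illustrative 62-gene skeletal dysplasia panel. The full curated panel used
# in diagnostic practice is not redistributed; HSPG2 is the gene of interest
# and the remaining symbols are placeholders drawn from well-known skeletal
# dysplasia genes.
HSPG2
ACAN
AGPS
ALPL
ANKH
ARSB
ARSE
B3GALT6
B4GALT7
BMP2
BMPR1B
CANT1
CHST3
COL10A1
COL11A1
COL11A2
COL1A1
COL1A2
COL2A1
COL9A1
COL9A2
COL9A3
COMP
DYNC2H1
EBP
ENPP1
EVC
EVC2
FGFR1
FGFR2
FGFR3
FLNA
FLNB
GALNS
GDF5
GNAS
GNPAT
GUSB
HOXD13
IDUA
IFT80
LBR
MATN3
MGP
NOG
NPR2
PEX7
PTH1R
RMRP
ROR2
RUNX2
SBDS
SHOX
SLC26A2
SMARCAL1
SOX9
TBX3
TBX5
TRIP11
TRPV4
WNT5A
XYLT1
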