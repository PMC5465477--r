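# published per-subunit desflurane contact probabilities (%) at the
# intrasubunit (TM1) binding region, with the reported cross-subunit
# mean and standard deviation; sampled every 1 ns, 3.5 angstrom cutoff
residue_name,residue_seq,A,B,C,D,E,mean_reported,sd_reported
TYR,119,10,23,90,71,14,41.6,36.4
PRO,120,28,22,97,98,33,55.6,38.4
PHE,121,61,10,25,44,90,46.0,31.2
TYR,197,11,38,80,86,8,44.6,37.0
ILE,201,12,42,97,92,10,50.6,42.1
ILE,202,66,42,96,100,96,80.0,25.2
MET,205,16,35,77,81,28,47.4,29.7
LYS,206,58,14,3,4,87,33.2,37.6
VAL,242,11,40,86,88,11,47.2,38.2
TYR,254,66,8,30,57,94,51.0,33.1
THR,255,23,45,97,97,43,61.0,34.0
ILE,258,67,36,70,88,98,71.8,23.8
ASN,307,51,3,2,4,67,25.4,31.2
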