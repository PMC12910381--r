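# Common contaminant proteins (keratins, trypsin, serum albumin, etc.)
# One UniProt accession per line.
P04264
P35908
P13645
P35527
P02533
P08779
P02768
P00761
P00760
Q29443
P02769
P01966
P02070
Q3SX14
P19013
Q7Z794
P08729
P02538
O43790
P78386
Q14532
Q92764
O76011
Q14525
O76013
O76014
O76015
P25908
Q01546
P07477
P02788
P61626
P04745
P12763
Q2KIS7
P00711
P02662
P02663
P02666
P02668
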