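# Synthetic stand-in for the 84-gene MIS-C panel (the published panel sits in
# unavailable supplementary material). Union of the 19 genes carrying
# prioritized panel variants, the five immunity genes reported for Middle
# Eastern MIS-C cohorts, and the genes recovered in the differential-expression
# overlap. Supply your own panel file for real analyses.
AP3B1
ATM
C6
CR2
DCLRE1C
DDX60
DOCK8
IFIH1
IFNA6
IFNB1
IL22RA2
IRAK3
LIG4
LRBA
LY9
LYST
NLRP12
NOD2
PSTPIP1
RASSF3
RNASEL
STING1
TLR3
TLR6
TMEM154
TTC7A
UNC13D
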