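# Arabidopsis thaliana phytohormone pathway gene groups (hormone -> category
# -> genes) for master-regulator screening against real promoter sets.
#
# Only genes individually named in the primary literature on this screen are
# listed by symbol; the remaining members of the 32-gene biosynthesis panel
# are placeholders flagged `unconfirmed_*` and must be replaced with the
# user's own gene list before a real analysis. Edit freely - group
# membership is configuration, not code.
SA:
  biosynthesis:
    - ICS1
    - EDS5
    - WIN3
    - PAL1
    - PAL3
    - CM2
    - unconfirmed_SA_1
    - unconfirmed_SA_2
  signaling:
    - NPR1
    - PR1
JA:
  biosynthesis:
    - LOX1
    - JAZ10
    - AOC1
    - OPR1
    - unconfirmed_JA_1
    - unconfirmed_JA_2
    - unconfirmed_JA_3
    - unconfirmed_JA_4
  signaling:
    - COI1
    - JAZ
    - MYC2
ABA:
  biosynthesis:
    - NCED1
    - NCED5
    - NCED9
    - AAO3
    - ZEP
    - unconfirmed_ABA_1
    - unconfirmed_ABA_2
    - unconfirmed_ABA_3
  signaling:
    - PP2C
    - SnRK2
ET:
  biosynthesis:
    - ACS1
    - ACS12
    - unconfirmed_ET_1
    - unconfirmed_ET_2
    - unconfirmed_ET_3
    - unconfirmed_ET_4
    - unconfirmed_ET_5
    - unconfirmed_ET_6
  signaling:
    - EBF1
    - EBF2
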