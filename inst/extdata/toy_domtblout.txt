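#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
t1                   -             52 seed                 -             26   1.5e-42  130.2  19.4   1   2   3.3e-23   3.3e-23   68.3   5.7     1    26     1    26     1    26 1.00 -
t1                   -             52 seed                 -             26   1.5e-42  130.2  19.4   2   2   3.3e-23   3.3e-23   68.3   5.7     1    26    27    52    27    52 1.00 -
t2                   -             30 seed                 -             26   8.8e-23   66.9   5.7   1   1   1.2e-22   1.2e-22   66.5   5.7     1    26     1    26     1    26 1.00 -
#
# Program:         hmmsearch
# Version:         3.4 (Aug 2023)
# Pipeline mode:   SEARCH
# Query file:      toy.hmm
# Target file:     targets.fa
# Option settings: hmmsearch --domtblout dom.txt -E 1000 toy.hmm targets.fa 
# Current dir:     /root/pkg/scratch/hmm
# Date:            Mon Sep 28 18:19:55 2026
# [ok]
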