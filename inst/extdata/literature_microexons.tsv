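gene	chrom	start	length	probability
ROBO1	chr3	78696778	27	0.739
ANK2	chr4	114158754	24	0.744
CR1	chr1	207795317	24	0.402
PICALM	chr11	85689112	24	0.844
FERMT2	chr14	53327731	21	0.745
ITSN1	chr21	35174733	15	0.631
ZFYVE27	chr10	99512613	21	0.116
L1CAM	chrX	153141083	21	0.811
DTNA	chr18	32401063	9	0.581
SHANK2	chr11	70788698	12	0.711
APBB1	chr11	6423206	6	0.776
APBB2	chr4	40824046	21	0.802
APBB3	chr5	139941428	6	0.717
TRAPPC9	chr8	141436713	27	0.865
RAB3GAP1	chr2	135809868	27	0.731
BIN1	chr2	127810997	24	0.740
DOCK9	chr13	99461376	6	0.663
MEF2D	chr1	156446285	21	0.120
KDM1A	chr1	23385839	12	0.717
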