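# 16S rRNA domain boundaries for SSU head/body motion analysis.
# Residue ranges are inclusive, author numbering.
# Ecoli-16S: head = 3' major domain (930-1390), body = remainder of 16S.
# Sac-16S: ported from Ecoli-16S with piecewise offsets anchored on
#   residue correspondences between the two numberings:
#   head anchor  Sac G1307 <-> E. coli G1338  (offset -31)
#   body anchor  Sac G496  <-> E. coli G530   (offset -34)
scheme	domain	start	end
Ecoli-16S	head	930	1390
Ecoli-16S	body	1	929
Ecoli-16S	body	1391	1542
Sac-16S	head	899	1359
Sac-16S	body	1	898
Sac-16S	body	1360	1508
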