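raw	canonical
rrn16	rrs
rrn16s	rrs
rrn18	rrs
16s	rrs
16s rrna	rrs
16s ribosomal rna	rrs
rrn23	rrl
rrn23s	rrl
23s	rrl
23s rrna	rrl
23s ribosomal rna	rrl
rrn5	rrf
rrn5s	rrf
5s	rrf
5s rrna	rrf
5s ribosomal rna	rrf
rbcl-a	rbcL
psba1	psbA
trnm-cau	trnMe(cau)
trnme-cau	trnMe(cau)
trnfm-cau	trnMf(cau)
trnmf-cau	trnMf(cau)
infa	infA
ycf12	ycf12
psb30	ycf12
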