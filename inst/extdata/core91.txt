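accD
atpA
atpB
atpE
atpF
atpH
atpI
cemA
clpP
ftsH
petA
petB
petD
petG
psaA
psaB
psaC
psaI
psaJ
psaM
psbA
psbB
psbC
psbD
psbE
psbF
psbH
psbI
psbJ
psbK
psbL
psbM
psbN
psbT
psbZ
rbcL
rpl2
rpl5
rpl12
rpl14
rpl16
rpl19
rpl20
rpl23
rpl36
rpoA
rpoB
rpoC1
rpoC2
rps2
rps3
rps7
rps8
rps9
rps11
rps12
rps18
rps19
rrf
rrl
rrs
tufA
ycf1
ycf3
ycf4
ycf20
trnA(ugc)
trnC(gca)
trnD(guc)
trnE(uuc)
trnF(gaa)
trnG(gcc)
trnG(ucc)
trnH(gug)
trnI(gau)
trnK(uuu)
trnL(uaa)
trnL(uag)
trnMe(cau)
trnMf(cau)
trnN(guu)
trnP(ugg)
trnQ(uug)
trnR(ucu)
trnR(acg)
trnS(gcu)
trnS(uga)
trnT(ugu)
trnV(uac)
trnW(cca)
trnY(gua)
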