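type_a,type_b,score,significant,complementation
cnP,CNp,0.62,TRUE,3
CnP,cNp,0.40,TRUE,3
cNp,Cnp,0.34,TRUE,2
CNP,cnp,0.26,TRUE,3
cNP,Cnp,0.23,TRUE,3
CnP,CNp,0.20,FALSE,2
cNP,CNp,0.20,FALSE,2
CNp,cnp,0.17,FALSE,2
cNP,CnP,0.14,FALSE,2
cnP,Cnp,0.10,FALSE,2
CNP,cNp,0.09,FALSE,2
CNp,cNp,0.08,FALSE,1
cNP,cNp,0.08,FALSE,1
CNp,Cnp,0.07,FALSE,1
CNP,cNP,0.07,FALSE,1
Cnp,cnp,0.06,FALSE,1
CnP,cnP,0.06,FALSE,1
cNP,cnP,0.05,FALSE,1
CnP,cnp,0.05,FALSE,2
CNP,CnP,0.05,FALSE,1
cNp,cnp,0.05,FALSE,1
CNP,cnP,0.05,FALSE,2
cnP,cNp,0.04,FALSE,2
cNP,cnp,0.03,FALSE,2
CnP,Cnp,0.02,FALSE,1
cnP,cnp,0.02,FALSE,1
CNP,Cnp,0.02,FALSE,2
CNP,CNp,0.02,FALSE,1
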