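id,arm,time,event
Cef1,Cefixime,0.25,failure
Cef10,Cefixime,0.25,failure
Cef11,Cefixime,0.25,failure
Cef12,Cefixime,0.25,failure
Cef13,Cefixime,0.25,failure
Cef14,Cefixime,0.25,failure
Cef15,Cefixime,0.25,failure
Cef16,Cefixime,0.25,failure
Cef17,Cefixime,0.25,failure
Cef18,Cefixime,0.25,failure
Cef19,Cefixime,0.25,failure
Cef2,Cefixime,0.25,failure
Cef20,Cefixime,0.25,failure
Cef21,Cefixime,0.75,relapse
Cef22,Cefixime,0.75,relapse
Cef23,Cefixime,0.75,relapse
Cef24,Cefixime,0.75,relapse
Cef25,Cefixime,0.75,relapse
Cef26,Cefixime,0.75,relapse
Cef27,Cefixime,1,censor
Cef28,Cefixime,1,censor
Cef29,Cefixime,1,censor
Cef3,Cefixime,0.25,failure
Cef30,Cefixime,1,censor
Cef31,Cefixime,1,censor
Cef32,Cefixime,1,censor
Cef33,Cefixime,1,censor
Cef34,Cefixime,1,censor
Cef35,Cefixime,1,censor
Cef36,Cefixime,1,censor
Cef37,Cefixime,1,censor
Cef38,Cefixime,1,censor
Cef39,Cefixime,1,censor
Cef4,Cefixime,0.25,failure
Cef40,Cefixime,1,censor
Cef41,Cefixime,1,censor
Cef42,Cefixime,1,censor
Cef43,Cefixime,1,censor
Cef44,Cefixime,1,censor
Cef45,Cefixime,1,censor
Cef46,Cefixime,1,censor
Cef47,Cefixime,1,censor
Cef48,Cefixime,1,censor
Cef49,Cefixime,1,censor
Cef5,Cefixime,0.25,failure
Cef50,Cefixime,1,censor
Cef51,Cefixime,1,censor
Cef52,Cefixime,1,censor
Cef53,Cefixime,1,censor
Cef54,Cefixime,1,censor
Cef55,Cefixime,1,censor
Cef56,Cefixime,1,censor
Cef57,Cefixime,1,censor
Cef58,Cefixime,1,censor
Cef59,Cefixime,1,censor
Cef6,Cefixime,0.25,failure
Cef60,Cefixime,1,censor
Cef61,Cefixime,1,censor
Cef62,Cefixime,1,censor
Cef63,Cefixime,1,censor
Cef64,Cefixime,1,censor
Cef65,Cefixime,1,censor
Cef66,Cefixime,1,censor
Cef67,Cefixime,1,censor
Cef68,Cefixime,1,censor
Cef69,Cefixime,1,censor
Cef7,Cefixime,0.25,failure
Cef70,Cefixime,1,censor
Cef71,Cefixime,1,censor
Cef72,Cefixime,1,censor
Cef73,Cefixime,1,censor
Cef74,Cefixime,1,censor
Cef75,Cefixime,1,censor
Cef76,Cefixime,1,censor
Cef77,Cefixime,1,censor
Cef8,Cefixime,0.25,failure
Cef9,Cefixime,0.25,failure
Gat1,Gatifloxacin,0.25,failure
Gat10,Gatifloxacin,1,censor
Gat11,Gatifloxacin,1,censor
Gat12,Gatifloxacin,1,censor
Gat13,Gatifloxacin,1,censor
Gat14,Gatifloxacin,1,censor
Gat15,Gatifloxacin,1,censor
Gat16,Gatifloxacin,1,censor
Gat17,Gatifloxacin,1,censor
Gat18,Gatifloxacin,1,censor
Gat19,Gatifloxacin,1,censor
Gat2,Gatifloxacin,0.75,relapse
Gat20,Gatifloxacin,1,censor
Gat21,Gatifloxacin,1,censor
Gat22,Gatifloxacin,1,censor
Gat23,Gatifloxacin,1,censor
Gat24,Gatifloxacin,1,censor
Gat25,Gatifloxacin,1,censor
Gat26,Gatifloxacin,1,censor
Gat27,Gatifloxacin,1,censor
Gat28,Gatifloxacin,1,censor
Gat29,Gatifloxacin,1,censor
Gat3,Gatifloxacin,0.75,relapse
Gat30,Gatifloxacin,1,censor
Gat31,Gatifloxacin,1,censor
Gat32,Gatifloxacin,1,censor
Gat33,Gatifloxacin,1,censor
Gat34,Gatifloxacin,1,censor
Gat35,Gatifloxacin,1,censor
Gat36,Gatifloxacin,1,censor
Gat37,Gatifloxacin,1,censor
Gat38,Gatifloxacin,1,censor
Gat39,Gatifloxacin,1,censor
Gat4,Gatifloxacin,1,censor
Gat40,Gatifloxacin,1,censor
Gat41,Gatifloxacin,1,censor
Gat42,Gatifloxacin,1,censor
Gat43,Gatifloxacin,1,censor
Gat44,Gatifloxacin,1,censor
Gat45,Gatifloxacin,1,censor
Gat46,Gatifloxacin,1,censor
Gat47,Gatifloxacin,1,censor
Gat48,Gatifloxacin,1,censor
Gat49,Gatifloxacin,1,censor
Gat5,Gatifloxacin,1,censor
Gat50,Gatifloxacin,1,censor
Gat51,Gatifloxacin,1,censor
Gat52,Gatifloxacin,1,censor
Gat53,Gatifloxacin,1,censor
Gat54,Gatifloxacin,1,censor
Gat55,Gatifloxacin,1,censor
Gat56,Gatifloxacin,1,censor
Gat57,Gatifloxacin,1,censor
Gat58,Gatifloxacin,1,censor
Gat59,Gatifloxacin,1,censor
Gat6,Gatifloxacin,1,censor
Gat60,Gatifloxacin,1,censor
Gat61,Gatifloxacin,1,censor
Gat62,Gatifloxacin,1,censor
Gat63,Gatifloxacin,1,censor
Gat64,Gatifloxacin,1,censor
Gat65,Gatifloxacin,1,censor
Gat66,Gatifloxacin,1,censor
Gat67,Gatifloxacin,1,censor
Gat68,Gatifloxacin,1,censor
Gat69,Gatifloxacin,1,censor
Gat7,Gatifloxacin,1,censor
Gat70,Gatifloxacin,1,censor
Gat71,Gatifloxacin,1,censor
Gat72,Gatifloxacin,1,censor
Gat73,Gatifloxacin,1,censor
Gat74,Gatifloxacin,1,censor
Gat75,Gatifloxacin,1,censor
Gat76,Gatifloxacin,1,censor
Gat77,Gatifloxacin,1,censor
Gat78,Gatifloxacin,1,censor
Gat79,Gatifloxacin,1,censor
Gat8,Gatifloxacin,1,censor
Gat80,Gatifloxacin,1,censor
Gat81,Gatifloxacin,1,censor
Gat82,Gatifloxacin,1,censor
Gat83,Gatifloxacin,1,censor
Gat84,Gatifloxacin,1,censor
Gat85,Gatifloxacin,1,censor
Gat86,Gatifloxacin,1,censor
Gat87,Gatifloxacin,1,censor
Gat88,Gatifloxacin,1,censor
Gat89,Gatifloxacin,1,censor
Gat9,Gatifloxacin,1,censor
Gat90,Gatifloxacin,1,censor
Gat91,Gatifloxacin,1,censor
Gat92,Gatifloxacin,1,censor
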