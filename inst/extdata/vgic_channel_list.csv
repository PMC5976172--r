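gene,subfamily
Kcna1,Kv (voltage-gated K+)
Kcna2,Kv (voltage-gated K+)
Kcna3,Kv (voltage-gated K+)
Kcna4,Kv (voltage-gated K+)
Kcna5,Kv (voltage-gated K+)
Kcna6,Kv (voltage-gated K+)
Kcna7,Kv (voltage-gated K+)
Kcna10,Kv (voltage-gated K+)
Kcnb1,Kv (voltage-gated K+)
Kcnb2,Kv (voltage-gated K+)
Kcnc1,Kv (voltage-gated K+)
Kcnc2,Kv (voltage-gated K+)
Kcnc3,Kv (voltage-gated K+)
Kcnc4,Kv (voltage-gated K+)
Kcnd1,Kv (voltage-gated K+)
Kcnd2,Kv (voltage-gated K+)
Kcnd3,Kv (voltage-gated K+)
Kcnf1,Kv (voltage-gated K+)
Kcng1,Kv (voltage-gated K+)
Kcng2,Kv (voltage-gated K+)
Kcng3,Kv (voltage-gated K+)
Kcng4,Kv (voltage-gated K+)
Kcnh1,Kv (voltage-gated K+)
Kcnh2,Kv (voltage-gated K+)
Kcnh3,Kv (voltage-gated K+)
Kcnh4,Kv (voltage-gated K+)
Kcnh5,Kv (voltage-gated K+)
Kcnh6,Kv (voltage-gated K+)
Kcnh7,Kv (voltage-gated K+)
Kcnh8,Kv (voltage-gated K+)
Kcnq1,Kv (voltage-gated K+)
Kcnq2,Kv (voltage-gated K+)
Kcnq3,Kv (voltage-gated K+)
Kcnq4,Kv (voltage-gated K+)
Kcnq5,Kv (voltage-gated K+)
Kcns1,Kv (voltage-gated K+)
Kcns2,Kv (voltage-gated K+)
Kcns3,Kv (voltage-gated K+)
Kcnv1,Kv (voltage-gated K+)
Kcnv2,Kv (voltage-gated K+)
Kcnma1,KCa (Ca2+- and Na+-activated K+)
Kcnn1,KCa (Ca2+- and Na+-activated K+)
Kcnn2,KCa (Ca2+- and Na+-activated K+)
Kcnn3,KCa (Ca2+- and Na+-activated K+)
Kcnn4,KCa (Ca2+- and Na+-activated K+)
Kcnt1,KCa (Ca2+- and Na+-activated K+)
Kcnt2,KCa (Ca2+- and Na+-activated K+)
Kcnu1,KCa (Ca2+- and Na+-activated K+)
Kcnj1,Kir (inwardly rectifying K+)
Kcnj2,Kir (inwardly rectifying K+)
Kcnj12,Kir (inwardly rectifying K+)
Kcnj4,Kir (inwardly rectifying K+)
Kcnj14,Kir (inwardly rectifying K+)
Kcnj3,Kir (inwardly rectifying K+)
Kcnj6,Kir (inwardly rectifying K+)
Kcnj9,Kir (inwardly rectifying K+)
Kcnj5,Kir (inwardly rectifying K+)
Kcnj10,Kir (inwardly rectifying K+)
Kcnj15,Kir (inwardly rectifying K+)
Kcnj16,Kir (inwardly rectifying K+)
Kcnj8,Kir (inwardly rectifying K+)
Kcnj11,Kir (inwardly rectifying K+)
Kcnj13,Kir (inwardly rectifying K+)
Kcnk1,K2P (two-pore domain K+)
Kcnk2,K2P (two-pore domain K+)
Kcnk3,K2P (two-pore domain K+)
Kcnk4,K2P (two-pore domain K+)
Kcnk5,K2P (two-pore domain K+)
Kcnk6,K2P (two-pore domain K+)
Kcnk7,K2P (two-pore domain K+)
Kcnk9,K2P (two-pore domain K+)
Kcnk10,K2P (two-pore domain K+)
Kcnk12,K2P (two-pore domain K+)
Kcnk13,K2P (two-pore domain K+)
Kcnk15,K2P (two-pore domain K+)
Kcnk16,K2P (two-pore domain K+)
Kcnk17,K2P (two-pore domain K+)
Kcnk18,K2P (two-pore domain K+)
Cacna1a,CaV (voltage-gated Ca2+)
Cacna1b,CaV (voltage-gated Ca2+)
Cacna1c,CaV (voltage-gated Ca2+)
Cacna1d,CaV (voltage-gated Ca2+)
Cacna1e,CaV (voltage-gated Ca2+)
Cacna1f,CaV (voltage-gated Ca2+)
Cacna1g,CaV (voltage-gated Ca2+)
Cacna1h,CaV (voltage-gated Ca2+)
Cacna1i,CaV (voltage-gated Ca2+)
Cacna1s,CaV (voltage-gated Ca2+)
Scn1a,NaV (voltage-gated Na+)
Scn2a,NaV (voltage-gated Na+)
Scn3a,NaV (voltage-gated Na+)
Scn4a,NaV (voltage-gated Na+)
Scn5a,NaV (voltage-gated Na+)
Scn8a,NaV (voltage-gated Na+)
Scn9a,NaV (voltage-gated Na+)
Scn10a,NaV (voltage-gated Na+)
Scn11a,NaV (voltage-gated Na+)
Scn7a,NaV (voltage-gated Na+)
Hcn1,HCN (hyperpolarization-activated cyclic nucleotide-gated)
Hcn2,HCN (hyperpolarization-activated cyclic nucleotide-gated)
Hcn3,HCN (hyperpolarization-activated cyclic nucleotide-gated)
Hcn4,HCN (hyperpolarization-activated cyclic nucleotide-gated)
Cnga1,CNG (cyclic nucleotide-gated)
Cnga2,CNG (cyclic nucleotide-gated)
Cnga3,CNG (cyclic nucleotide-gated)
Cnga4,CNG (cyclic nucleotide-gated)
Cngb1,CNG (cyclic nucleotide-gated)
Cngb3,CNG (cyclic nucleotide-gated)
Catsper1,CatSper and two-pore
Catsper2,CatSper and two-pore
Catsper3,CatSper and two-pore
Catsper4,CatSper and two-pore
Tpcn1,CatSper and two-pore
Tpcn2,CatSper and two-pore
Ryr1,RyR (ryanodine receptor)
Ryr2,RyR (ryanodine receptor)
Ryr3,RyR (ryanodine receptor)
Trpa1,TRP (transient receptor potential)
Trpc1,TRP (transient receptor potential)
Trpc2,TRP (transient receptor potential)
Trpc3,TRP (transient receptor potential)
Trpc4,TRP (transient receptor potential)
Trpc5,TRP (transient receptor potential)
Trpc6,TRP (transient receptor potential)
Trpc7,TRP (transient receptor potential)
Trpm1,TRP (transient receptor potential)
Trpm2,TRP (transient receptor potential)
Trpm3,TRP (transient receptor potential)
Trpm4,TRP (transient receptor potential)
Trpm5,TRP (transient receptor potential)
Trpm6,TRP (transient receptor potential)
Trpm7,TRP (transient receptor potential)
Trpm8,TRP (transient receptor potential)
Trpv1,TRP (transient receptor potential)
Trpv2,TRP (transient receptor potential)
Trpv3,TRP (transient receptor potential)
Trpv4,TRP (transient receptor potential)
Trpv5,TRP (transient receptor potential)
Trpv6,TRP (transient receptor potential)
Mcoln1,TRP (transient receptor potential)
Mcoln2,TRP (transient receptor potential)
Mcoln3,TRP (transient receptor potential)
Pkd2,TRP (transient receptor potential)
Pkd2l1,TRP (transient receptor potential)
Pkd2l2,TRP (transient receptor potential)
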