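trinuc	count
ACA	4016728
ACC	2238472
ACG	555088
ACT	3092518
ATA	3262503
ATC	3095819
ATG	2568313
ATT	3211061
CCA	3781287
CCC	3084894
CCG	604169
CCT	3256662
CTA	2512306
CTC	2962264
CTG	3302410
CTT	4392050
GCA	2477852
GCC	3356537
GCG	400757
GCT	2262407
GTA	2621945
GTC	2906765
GTG	2874536
GTT	3579291
TCA	3466830
TCC	3600205
TCG	735088
TCT	3306453
TTA	2813236
TTC	3156553
TTG	3908590
TTT	2843455
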