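group,stat,derivative,feature
normal,mean,0,Compactness
normal,mean,0,FLEW
normal,mean,0,RDF
normal,mean,0,AMoM_LCQT_2
normal,mean,0,AMoM_LCQT_7
normal,mean,0,AMoM_LCQT_8
normal,mean,0,AMoM_LCQT_9
normal,sd,0,Compactness
normal,sd,0,MFCC_0
normal,sd,0,MFCC_3
normal,sd,0,MFCC_4
normal,sd,0,MFCC_5
normal,sd,0,MFCC_6
normal,sd,0,MFCC_7
normal,sd,0,MFCC_8
normal,sd,0,MFCC_9
normal,sd,0,MFCC_10
normal,sd,0,MFCC_11
normal,sd,0,LPC_6
normal,sd,0,LPC_7
normal,sd,0,AMoM_MFCC_0
normal,sd,0,AMoM_MFCC_1
normal,sd,0,AMoM_MFCC_4
normal,sd,0,AMoM_MFCC_6
normal,sd,0,AMoM_LCQT_0
normal,sd,0,AMoM_LCQT_2
normal,sd,0,AMoM_LCQT_4
normal,sd,0,AMoM_LCQT_7
normal,sd,0,AMoM_LCQT_8
normal,sd,0,AMoM_LCQT_9
normal,sd,0,AMoM_CQMFCC_2
normal,sd,0,AMoM_CQMFCC_4
normal,sd,0,AMoM_CQMFCC_7
normal,sd,0,sb1
normal,sd,0,sb2
normal,sd,0,sb3
normal,sd,0,sb4
normal,sd,0,sb5
normal,sd,0,sb6
normal,sd,0,sb7
normal,sd,0,sb8
normal,sd,0,dBA
normal,sd,0,dBC
normal,sd,0,dB
normal,sd,0,peak_dB
normal,sd,0,peak_dBA
normal,sd,0,peak_dBC
normal,sd,1,Compactness
normal,sd,1,FLEW
normal,sd,1,MFCC_0
normal,sd,1,MFCC_2
normal,sd,1,MFCC_3
normal,sd,1,MFCC_5
normal,sd,1,MFCC_6
normal,sd,1,MFCC_7
normal,sd,1,MFCC_8
normal,sd,1,MFCC_9
normal,sd,1,MFCC_10
normal,sd,1,MFCC_11
normal,sd,1,MFCC_12
normal,min,0,sb6
normal,min,0,sb8
moderate,sd,0,FLEW
moderate,sd,0,MFCC_1
moderate,sd,1,ZC
moderate,sd,1,SF_ZC
moderate,sd,1,MFCC_1
moderate,sd,1,LPC_2
moderate,sd,1,LPC_5
severe,mean,0,SF
severe,mean,0,MM_0
severe,mean,0,AMoM_0
severe,mean,0,AMoM_3
severe,mean,0,AMoM_7
severe,mean,0,AMoM_MFCC_3
severe,mean,0,AMoM_LCQT_2
severe,mean,0,AMoM_LCQT_3
severe,mean,0,AMoM_LCQT_7
severe,mean,0,AMoM_LCQT_8
severe,mean,0,AMoM_LCQT_9
severe,mean,0,AMoM_CQMFCC_3
severe,mean,0,AMoM_CQMFCC_5
severe,mean,0,AMoM_CQMFCC_9
severe,sd,0,SF
severe,sd,0,SV
severe,sd,0,RMS
severe,sd,0,ZC
severe,sd,0,SF_ZC
severe,sd,0,SF_FFT
severe,sd,0,LPC_1
severe,sd,0,MM_0
severe,sd,0,RDF
severe,sd,0,AMoM_1
severe,sd,0,AMoM_3
severe,sd,0,AMoM_6
severe,sd,0,AMoM_7
severe,sd,0,AMoM_8
severe,sd,0,AMoM_MFCC_0
severe,sd,0,AMoM_MFCC_1
severe,sd,0,AMoM_MFCC_3
severe,sd,0,AMoM_MFCC_4
severe,sd,0,AMoM_MFCC_6
severe,sd,0,AMoM_LCQT_0
severe,sd,0,AMoM_LCQT_1
severe,sd,0,AMoM_LCQT_2
severe,sd,0,AMoM_LCQT_3
severe,sd,0,AMoM_LCQT_4
severe,sd,0,AMoM_LCQT_6
severe,sd,0,AMoM_LCQT_7
severe,sd,0,AMoM_LCQT_8
severe,sd,0,AMoM_LCQT_9
severe,sd,0,AMoM_CQMFCC_1
severe,sd,0,AMoM_CQMFCC_2
severe,sd,0,AMoM_CQMFCC_3
severe,sd,0,AMoM_CQMFCC_4
severe,sd,0,AMoM_CQMFCC_6
severe,sd,0,AMoM_CQMFCC_7
severe,sd,0,dBA
severe,sd,0,dBC
severe,sd,0,dB
severe,sd,0,peak_dB
severe,sd,0,peak_dBA
severe,sd,0,peak_dBC
severe,sd,1,SF
severe,sd,1,SV
severe,sd,1,RMS
severe,sd,1,SF_FFT
severe,sd,1,LPC_1
severe,sd,1,LPC_7
severe,sd,1,MM_0
severe,sd,1,MM_2
severe,sd,1,RDF
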