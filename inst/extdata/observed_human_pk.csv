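stage,parameter,observed_mean,observed_sd
normal,auc,268,71.5
normal,cmax,94.2,25.3
normal,tmax,0.75,NA
moderate,auc,396,154
moderate,cmax,104,47.5
moderate,tmax,0.75,NA
severe,auc,615,214
severe,cmax,111,28.6
severe,tmax,0.75,NA
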