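drug,formulation,cmax,tmax,auc
stiripentol,nlc,12.3,2.0,86.2
stiripentol,commercial,16.7,2.0,89.2
cannabidiol,nlc,1.27,1.0,8.0
cannabidiol,commercial,0.61,0.5,5.4
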