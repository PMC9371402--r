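comparison,model,aic,bic,log_lik,lrt,df,p_value
2pl_vs_3pl,2PL,4766.76,4935.06,-2333.38,NA,NA,NA
2pl_vs_3pl,3PL,4816.76,5069.21,-2333.38,0,25,1
rasch_vs_2pl,Rasch,4890.91,4975.06,-2420.46,NA,NA,NA
rasch_vs_2pl,2PL,4766.76,4935.06,-2333.38,174.15,25,0.001
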