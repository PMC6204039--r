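species,event,ci_low,ci_high,lit_low,lit_high,lit_peak,source
Vitvi,gamma,1.05,1.25,NA,NA,1.22,Tang2008
Poptr,gamma,1.35,1.64,NA,NA,1.54,Tang2008
Poptr,salicoid,0.30,0.38,0.15,0.40,0.27,Vanneste2014;Tang2008
Glyma,gamma,1.43,1.54,NA,NA,1.50,Schmutz2010
Glyma,early_legume,NA,NA,0.40,0.80,NA,Schmutz2010
Glyma,soybean_specific,0.19,0.22,0.06,0.39,NA,Schmutz2010
Solly,T,0.67,1.07,0.40,1.00,NA,Vanneste2014;TomatoGenomeConsortium2012
Soltu,T,0.55,0.86,0.40,1.00,NA,Vanneste2014
Elagu,tau,0.96,1.16,NA,NA,1.13,Jiao2014
Elagu,P,0.33,0.40,NA,NA,0.36,Jiao2014
Orysa,rho,0.85,0.90,0.60,1.00,0.86,Vanneste2014;Jiao2014
Sorbi,rho,0.94,1.01,0.60,1.30,NA,Vanneste2014
Phypa,Pp_WGD,0.69,0.87,0.50,0.90,NA,Rensing2008
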