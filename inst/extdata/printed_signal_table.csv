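drug,a,b,ror,ror_l,ror_u,ic,ic_l,ic_u,starred
atorvastatin,4160,78562,3.09,2.99,3.19,1.56,1.46,1.67,TRUE
rosuvastatin,1590,40501,2.27,2.16,2.39,1.15,0.98,1.32,TRUE
simvastatin,1514,29670,2.96,2.81,3.12,1.51,1.34,1.68,TRUE
pravastatin,220,6142,2.07,1.81,2.37,1.02,0.57,1.46,TRUE
fluvastatin,169,1415,6.90,5.89,8.10,2.65,2.08,3.13,TRUE
lovastatin,68,1419,2.77,2.17,3.53,1.43,0.59,2.19,TRUE
pitavastatin,52,1598,1.88,1.43,2.48,0.89,-0.04,1.77,FALSE
cerivastatin,6,26,13.33,5.49,32.49,3.46,-0.54,4.87,FALSE
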