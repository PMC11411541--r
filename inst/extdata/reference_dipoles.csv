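substance_id,name,mu,note
mee,methyl ethyl ether,1.17,approximate gas-phase literature value
dee,diethyl ether,1.15,approximate gas-phase literature value
acetone,acetone,2.88,approximate gas-phase literature value
butanone,2-butanone,2.78,approximate gas-phase literature value
propanal,propanal,2.52,approximate gas-phase literature value
butanal,butanal,2.72,approximate gas-phase literature value
etformate,ethyl formate,1.93,approximate gas-phase literature value
meacetate,methyl acetate,1.72,approximate gas-phase literature value
etacetate,ethyl acetate,1.78,approximate gas-phase literature value
clpropane1,1-chloropropane,2.05,approximate gas-phase literature value
clpropane2,2-chloropropane,2.17,approximate gas-phase literature value
clbutane1,1-chlorobutane,2.05,approximate gas-phase literature value
brpropane1,1-bromopropane,2.18,approximate gas-phase literature value
ipropane1,1-iodopropane,2.04,approximate gas-phase literature value
fpropane2,2-fluoropropane,1.96,approximate gas-phase literature value
tbucl,2-chloro-2-methylpropane,2.13,approximate gas-phase literature value
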