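solute,solvent,solubility_g_per_l,quantifiable,temperature_k,pressure_mpa,lower_bound,source
hesperetin,acetone,102.80,true,298.15,0.1,false,printed
hesperetin,methyl ethyl ketone,77.66,true,298.15,0.1,false,printed
hesperetin,methanol,35.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,ethyl lactate,30.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,methyl isobutyl ketone,25.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,n-propyl acetate,18.62,true,298.15,0.1,false,printed
hesperetin,ethanol,15.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,1-propanol,12.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,ethyl acetate,10.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,isopropyl acetate,9.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,n-butyl acetate,7.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,acetonitrile,6.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,1-octanol,4.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,diisopropyl ether,2.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,water,1.0,true,298.15,0.1,false,synthetic_stand_in
hesperetin,p-xylene,,false,298.15,0.1,false,unquantifiable
hesperetin,n-hexane,,false,298.15,0.1,false,unquantifiable
hesperetin,n-decane,,false,298.15,0.1,false,unquantifiable
hesperetin,cyclohexane,,false,298.15,0.1,false,unquantifiable
hesperetin,cyclooctane,,false,298.15,0.1,false,unquantifiable
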