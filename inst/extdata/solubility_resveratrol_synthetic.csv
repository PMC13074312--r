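solute,solvent,solubility_g_per_l,quantifiable,temperature_k,pressure_mpa,lower_bound,source
trans-resveratrol,methanol,100.0,true,298.15,0.1,true,printed_floor
trans-resveratrol,ethanol,100.0,true,298.15,0.1,true,printed_floor
trans-resveratrol,acetone,100.0,true,298.15,0.1,true,printed_floor
trans-resveratrol,methyl ethyl ketone,100.0,true,298.15,0.1,true,printed_floor
trans-resveratrol,1-propanol,33.38,true,298.15,0.1,false,printed
trans-resveratrol,methyl isobutyl ketone,31.82,true,298.15,0.1,false,printed
trans-resveratrol,ethyl lactate,27.14,true,298.15,0.1,false,printed
trans-resveratrol,ethyl acetate,20.89,true,298.15,0.1,false,printed
trans-resveratrol,1-octanol,5.0,true,298.15,0.1,false,synthetic_stand_in
trans-resveratrol,acetonitrile,5.0,true,298.15,0.1,false,synthetic_stand_in
trans-resveratrol,n-propyl acetate,12.0,true,298.15,0.1,false,synthetic_stand_in
trans-resveratrol,isopropyl acetate,10.0,true,298.15,0.1,false,synthetic_stand_in
trans-resveratrol,n-butyl acetate,8.0,true,298.15,0.1,false,synthetic_stand_in
trans-resveratrol,n-hexane,,false,298.15,0.1,false,unquantifiable
trans-resveratrol,n-decane,,false,298.15,0.1,false,unquantifiable
trans-resveratrol,cyclohexane,,false,298.15,0.1,false,unquantifiable
trans-resveratrol,cyclooctane,,false,298.15,0.1,false,unquantifiable
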