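variable,dist,location,scale,aggregation,exclude
age,normal,61,14,median,FALSE
ast,lognormal,3.7136,0.6,max,FALSE
alt,lognormal,3.2581,0.7,max,FALSE
bilirubin,lognormal,-0.6931,0.6,max,FALSE
inr,lognormal,0.1823,0.15,max,FALSE
aptt,lognormal,3.5553,0.25,max,FALSE
quick,normal,80,15,min,FALSE
lactate,lognormal,0.6931,0.4,max,FALSE
creatinine,lognormal,0,0.4,max,FALSE
urea,lognormal,3.0445,0.5,max,FALSE
urine_output,normal,1690,600,min,FALSE
platelets,lognormal,5.3181,0.45,min,FALSE
wbc,lognormal,2.3026,0.5,max,FALSE
crp,lognormal,2.5649,0.7,max,FALSE
lymphocytes_rel,lognormal,2.1972,0.5,min,FALSE
map,normal,85,10,min,FALSE
bp_sys,normal,125,15,min,FALSE
bp_dia,normal,65,10,min,FALSE
heart_rate,normal,81,15,max,FALSE
base_excess,normal,-1,3,min,FALSE
ph,normal,7.38,0.06,min,FALSE
pco2,normal,49,8,max,FALSE
horovitz,normal,260,90,min,FALSE
temperature,normal,37.6,0.7,max,FALSE
hemoglobin,normal,10.5,1.8,min,FALSE
glucose,lognormal,4.9416,0.3,max,FALSE
albumin,normal,2.8,0.6,min,FALSE
fibrinogen,lognormal,6.1092,0.35,min,FALSE
procalcitonin,lognormal,0.6931,1,max,FALSE
ntprobnp,lognormal,6.7788,1,max,FALSE
norepinephrine,lognormal,-2.3026,1.2,max,TRUE
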