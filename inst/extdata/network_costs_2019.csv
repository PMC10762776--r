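# Network-level PHC cost totals, nine Ethiopian regions, 2018/19, US$ millions.
# series: actual-cost extrapolation estimator (A1 catchment norms, A2 reported
# catchments, B utilization expansion) or the normative requirement.
series,level,clinical_labor,drugs_supplies,indirect,total
A1,health_post,105.4,161.0,0.0,266.4
A1,health_center,307.7,347.7,211.2,866.6
A1,primary_hospital,353.9,141.0,237.7,732.7
A2,health_post,86.9,130.8,0.0,217.7
A2,health_center,276.5,304.8,196.2,777.5
A2,primary_hospital,191.0,75.3,124.5,390.8
B,health_post,69.0,73.4,0.0,142.3
B,health_center,73.2,112.1,52.0,237.3
B,primary_hospital,27.7,12.4,17.0,57.2
normative,health_post,79.9,491.7,0.0,571.6
normative,health_center,177.1,894.1,345.2,1416.4
normative,primary_hospital,277.7,780.8,508.5,1567.0
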