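muscle_name,state,side,tendon_um,shortest_fiber_um,longest_fiber_um,tendon_extrapolated,shortest_fiber_extrapolated,longest_fiber_extrapolated
anterior medial inner,closed,averaged,140.04,185.18,370.45,0,0,0
anterior medial inner,open,averaged,156.58,399.52,522.22,0,1,1
anterior median outer,closed,averaged,20.73,100.52,105.46,0,0,0
anterior median outer,open,averaged,21.12,130.01,154.42,0,0,0
anterior outer,closed,averaged,29.69,113.01,235.38,0,0,0
anterior outer,open,averaged,28.66,236.06,319.53,0,0,0
lateral anterior,closed,averaged,33.31,143.12,258.94,0,0,0
lateral anterior,open,averaged,33.67,150.00,311.41,0,0,0
lateral posterior,closed,averaged,45.07,129.79,230.41,0,0,0
lateral posterior,open,averaged,40.33,123.20,265.74,0,0,0
posterior median,closed,averaged,91.43,199.25,312.83,0,0,0
posterior median,open,averaged,64.17,330.87,396.70,0,1,1
intercheliceral sclerite,closed,averaged,17.79,103.13,110.87,0,0,0
intercheliceral sclerite,open,averaged,30.48,86.21,288.48,0,0,0
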