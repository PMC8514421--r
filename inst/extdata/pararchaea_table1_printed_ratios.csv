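muscle_name,state,field,printed_ratio
anterior medial inner,closed,tendon,0.27
anterior medial inner,open,tendon,0.31
anterior medial inner,closed,shortest_fiber,0.37
anterior medial inner,open,shortest_fiber,0.81
anterior medial inner,closed,longest_fiber,0.74
anterior medial inner,open,longest_fiber,1.05
anterior median outer,closed,tendon,0.04
anterior median outer,open,tendon,0.05
anterior median outer,closed,shortest_fiber,0.20
anterior median outer,open,shortest_fiber,0.26
anterior median outer,closed,longest_fiber,0.21
anterior median outer,open,longest_fiber,0.31
anterior outer,closed,tendon,0.06
anterior outer,open,tendon,0.06
anterior outer,closed,shortest_fiber,0.23
anterior outer,open,shortest_fiber,0.48
anterior outer,closed,longest_fiber,0.47
anterior outer,open,longest_fiber,0.64
lateral anterior,closed,tendon,0.07
lateral anterior,open,tendon,0.07
lateral anterior,closed,shortest_fiber,0.29
lateral anterior,open,shortest_fiber,0.30
lateral anterior,closed,longest_fiber,0.52
lateral anterior,open,longest_fiber,0.63
lateral posterior,closed,tendon,0.09
lateral posterior,open,tendon,0.08
lateral posterior,closed,shortest_fiber,0.26
lateral posterior,open,shortest_fiber,0.25
lateral posterior,closed,longest_fiber,0.46
lateral posterior,open,longest_fiber,0.54
posterior median,closed,tendon,0.18
posterior median,open,tendon,0.13
posterior median,closed,shortest_fiber,0.40
posterior median,open,shortest_fiber,0.67
posterior median,closed,longest_fiber,0.63
posterior median,open,longest_fiber,0.80
intercheliceral sclerite,closed,tendon,0.04
intercheliceral sclerite,open,tendon,0.06
intercheliceral sclerite,closed,shortest_fiber,0.21
intercheliceral sclerite,open,shortest_fiber,0.17
intercheliceral sclerite,closed,longest_fiber,0.22
intercheliceral sclerite,open,longest_fiber,0.58
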