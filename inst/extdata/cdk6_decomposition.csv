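# Side-chain (S*) and backbone (B*) contributions to inhibitor-residue
# interactions (kcal/mol) for the four inhibitor-bound CDK6 systems;
# T* = S* + B* totals per interaction type; dG is the per-residue free energy.
system,residue,SvdW,BvdW,TvdW,Sele,Bele,Tele,Sgb,Bgb,Tgb,dG
LQQ-CDK6/Vcyclin,I19,-2.75,-0.95,-3.7,-0.22,-0.32,-0.54,0.18,1.5,1.68,-3.1
LQQ-CDK6/Vcyclin,V27,-1.53,-0.15,-1.68,-0.12,-0.07,-0.19,0.11,0.04,0.15,-1.94
LQQ-CDK6/Vcyclin,A41,-0.69,-0.2,-0.89,0.02,0.01,0.03,-0.02,0.11,0.09,-0.83
LQQ-CDK6/Vcyclin,F98,-1.15,-0.13,-1.28,0.21,0.17,0.38,-0.05,-0.04,-0.09,-1.1
LQQ-CDK6/Vcyclin,H100,-1.15,-0.34,-1.49,-0.86,-0.63,-1.49,1.12,0.14,1.26,-1.77
LQQ-CDK6/Vcyclin,V101,-0.92,-0.2,-1.12,0.01,-2.17,-2.16,-0.03,1.0,0.97,-2.37
LQQ-CDK6/Vcyclin,Q103,-1.02,-0.84,-1.86,-0.17,0.13,-0.04,0.23,-0.02,0.21,-1.83
LQQ-CDK6/Vcyclin,T107,-0.68,-0.08,-0.76,-0.53,0.1,-0.43,0.66,-0.22,0.43,-0.94
LQQ-CDK6/Vcyclin,L152,-2.32,-0.1,-2.41,-0.04,-0.03,-0.08,0.1,-0.08,0.02,-2.74
LQQ-CDK6,I19,-2.69,-0.62,-3.3,-0.19,-0.23,-0.42,0.2,0.88,1.09,-3.11
LQQ-CDK6,V27,-1.57,-0.15,-1.72,-0.08,-0.02,-0.1,0.09,0.02,0.11,-1.94
LQQ-CDK6,A41,-0.72,-0.22,-0.94,0.01,-0.03,-0.01,-0.01,0.15,0.14,-0.88
LQQ-CDK6,F98,-1.19,-0.13,-1.32,0.22,0.16,0.38,-0.06,-0.06,-0.12,-1.17
LQQ-CDK6,H100,-1.22,-0.34,-1.56,-2.49,-0.72,-3.21,1.88,0.21,2.09,-2.75
LQQ-CDK6,V101,-0.82,-0.18,-1.0,0.0,-2.41,-2.41,-0.02,1.1,1.08,-2.38
LQQ-CDK6,Q103,-0.96,-0.81,-1.77,-0.14,0.05,-0.09,0.16,-0.1,0.07,-1.91
LQQ-CDK6,T107,-0.71,-0.08,-0.79,-0.79,0.16,-0.63,0.92,-0.3,0.62,-1.0
LQQ-CDK6,L152,-2.36,-0.09,-2.46,-0.07,0.0,-0.07,0.14,-0.11,0.03,-2.78
AP9-CDK6/Vcyclin,I19,-2.36,-0.5,-2.86,-0.2,0.28,0.08,0.24,0.01,0.26,-2.95
AP9-CDK6/Vcyclin,V27,-1.68,-0.16,-1.84,-0.12,0.15,0.03,0.09,-0.27,-0.18,-2.22
AP9-CDK6/Vcyclin,A41,-0.73,-0.3,-1.03,0.07,-0.33,-0.26,-0.04,0.42,0.38,-0.98
AP9-CDK6/Vcyclin,F98,-1.43,-0.15,-1.58,-0.12,0.22,0.1,0.02,-0.14,-0.12,-1.68
AP9-CDK6/Vcyclin,V101,-1.0,-0.62,-1.62,-0.05,-2.65,-2.7,-0.01,1.7,1.69,-2.71
AP9-CDK6/Vcyclin,Q103,-0.91,-0.76,-1.67,-0.18,-0.8,-0.98,0.25,0.51,0.76,-2.0
AP9-CDK6/Vcyclin,L152,-2.51,-0.09,-2.6,-0.17,-0.2,-0.38,0.24,0.08,0.32,-2.95
AP9-CDK6,I19,-2.18,-0.39,-2.57,-0.23,0.2,-0.03,0.26,0.01,0.27,-2.76
AP9-CDK6,V27,-1.52,-0.15,-1.66,-0.12,0.16,0.03,0.11,-0.3,-0.18,-2.06
AP9-CDK6,A41,-0.62,-0.26,-0.88,0.07,-0.31,-0.24,-0.04,0.41,0.38,-0.81
AP9-CDK6,F98,-1.18,-0.17,-1.34,-0.12,0.23,0.11,0.12,-0.17,-0.05,-1.39
AP9-CDK6,V101,-0.93,-0.65,-1.58,-0.02,-2.35,-2.37,-0.04,1.7,1.66,-2.4
AP9-CDK6,Q103,-0.8,-0.69,-1.5,-0.15,-1.0,-1.15,0.2,0.69,0.88,-1.87
AP9-CDK6,L152,-2.38,-0.09,-2.47,-0.09,-0.2,-0.29,0.2,0.07,0.27,-2.82
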