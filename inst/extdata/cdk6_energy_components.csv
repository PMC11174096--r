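# QM/MM-GBSA binding free energy components (kcal/mol) for the four
# inhibitor-bound CDK6 systems; one row per system.  minus_TdS stores the
# -T*dS entropy penalty as a positive value; dH and dGbind are the printed
# derived values; *_se columns are standard errors.
system,dEele,dEvdw,dGgb,dGsurf,dGscf,minus_TdS,dH,dGbind,dEele_se,dEvdw_se,dGgb_se,dGsurf_se,dGscf_se,minus_TdS_se,dH_se
LQQ-CDK6/Vcyclin,0.09,-52.14,30.43,-5.90,-10.72,17.20,-38.23,-21.03,0.00,0.21,0.32,0.02,0.30,1.18,0.26
LQQ-CDK6,0.07,-51.73,28.75,-5.95,-11.54,20.98,-40.39,-19.41,0.00,0.21,0.32,0.02,0.28,1.05,0.28
AP9-CDK6/Vcyclin,0.08,-48.89,29.68,-5.90,-5.62,21.08,-30.62,-9.54,0.00,0.17,0.44,0.02,0.44,1.17,0.19
AP9-CDK6,0.08,-42.90,25.33,-5.26,-3.78,19.22,-26.52,-7.30,0.00,0.22,0.43,0.02,0.50,0.97,0.29
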