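beta_cons: 0.41999999999999998
beta_res_animal: 0.19
beta_res_plant: 0
eta_cons: -0.47999999999999998
eta_res: -0.66000000000000003
q: 0.5
c: 0.80000000000000004
gamma: 2
R_opt: 100
b0: 50
h0: 0.40000000000000002
e_P: 0.45000000000000001
e_A: 0.84999999999999998
x_A: 0.314
x_P: 0.13800000000000001
metab_exp: -0.25
r0: 1
growth_exp: -0.25
D: 0.25
v: 1 0.5
S_supply: 10 10
K: 0.14999999999999999 0.14999999999999999 0.14999999999999999 0.14999999999999999 0.14999999999999999 0.14999999999999999
K_nrow: 3
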