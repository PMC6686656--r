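# Example scenario config: the fig7 preset with a longer horizon.
# Schema: all 20 keys required; name/description optional.
name: fig7_long
description: ages 20-25 stratum, horizon stretched to 40 time units
alpha: 0.3
gamma: 0.5
beta: 0.05
lam: 0.47
b: 0.34
eta: 0.47
zeta: 0.16
mu1: 0.9
mu2: 0.92
u1: 0.04
u2: 0.29
S0: 15
I0: 30
T1_0: 27
T2_0: 12
N0: 104
R0_init: 20
t_start: 0
t_end: 40
M: 80
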