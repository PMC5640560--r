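# Photon interaction coefficients for liquid water (standard compilation
# values): mass attenuation mu/rho and mass energy-absorption mu_en/rho in
# cm^2/g on a keV grid; log-log interpolated in code. buildup_a is the
# coefficient of the linear energy-absorption buildup model
# B(mu*r) = 1 + a*mu*r used by the analytic point kernel; it is fixed by
# energy conservation, a = (mu/rho)/(mu_en/rho) - 1, so that the kernel
# integrates to unit absorbed fraction in an unbounded medium.
energy_keV,mu_rho_cm2g,mu_en_rho_cm2g,buildup_a
10,5.329,4.944,0.0779
15,1.673,1.374,0.2176
20,0.8096,0.5503,0.4712
30,0.3756,0.1557,1.4124
40,0.2683,0.06947,2.8621
50,0.2269,0.04223,4.3730
60,0.2059,0.03190,5.4545
80,0.1837,0.02597,6.0732
100,0.1707,0.02546,5.7047
150,0.1505,0.02764,4.4447
200,0.1370,0.02967,3.6178
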