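# Contrast-agent element table for the K-edge attenuation model
# mu_solute(E) [mm^-1] = c[mg/ml] * A * E^-3 * (r if E >= k_edge_keV else 1) * 1e-4
# k_edge_keV: tabulated K-shell binding energies.
# A [(cm^2/g) keV^3]: power-law amplitude anchored so the pre-edge mass
#   attenuation at E_K matches tabulated (NIST-magnitude) values; together
#   with the jump ratio r (post/pre mass attenuation at E_K) this is a
#   synthetic parametric model, not a reproduction of the full tables.
symbol,k_edge_kev,A,r
I,33.17,239043,5.47
Ba,37.44,261355,5.49
W,69.53,658917,4.94
Ca,4.04,1905,8.90
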