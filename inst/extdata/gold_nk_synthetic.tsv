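# Synthetic tabulation of gold optical constants in the visible / NIR.
# Reconstructed from commonly cited evaporated-film gold values
# (Johnson & Christy-type measurements, rounded to 2-3 significant digits)
# with smooth interpolation between anchor wavelengths. Intended only as an
# independent interpolation oracle for order-of-magnitude validation of the
# package's Drude-Lorentz gold fit; not a measurement record.
# Columns: wavelength_nm  n  k
500	0.97	1.87
520	0.62	2.10
550	0.43	2.46
575	0.30	2.88
600	0.25	3.09
633	0.18	3.43
650	0.17	3.59
675	0.16	3.80
700	0.14	4.10
750	0.14	4.50
800	0.15	4.95
850	0.17	5.30
900	0.20	5.70
1000	0.24	6.45
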