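nuclide	half_life	use
F-18	1.82890(23) h	diagnosis
Tc-99m	6.0067(10) h	diagnosis
I-131	8.0233(19) d	both
Lu-177	6.647(4) d	therapy
Y-90	2.6684(13) d	therapy
Ra-223	11.43(3) d	therapy
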