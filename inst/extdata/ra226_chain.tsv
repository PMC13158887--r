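# Uranium-series decay chain from Ra-226 to stable Pb-206 (linear; minor
# branches < 1% omitted). Half-lives and dominant gamma lines transcribed from
# standard nuclide data (NNDC/NuDat). Historical aliases are the classical
# "Radium A..G" names used in early dial-worker records.
# Columns: name, alias, half_life_value, half_life_unit (y/d/min/s/us, or
# "stable" in mode), mode (alpha/beta/stable), then repeated
# gamma_keV_i / gamma_yield_i pairs (yield as probability per decay; blank =
# no line above the 1e-4 cutoff retained here).
name	alias	half_life_value	half_life_unit	mode	gamma_keV_1	gamma_yield_1
Ra-226		1600	y	alpha	186.2	0.0364
Rn-222		3.8235	d	alpha
Po-218	Radium A	3.098	min	alpha
Pb-214	Radium B	26.8	min	beta	351.9	0.356
Bi-214	Radium C	19.9	min	beta	609.3	0.4544
Po-214	Radium C'	164.3	us	alpha
Pb-210	Radium D	22.2	y	beta	46.5	0.0425
Bi-210	Radium E	5.012	d	beta
Po-210	Radium F	138.376	d	alpha
Pb-206	Radium G			stable
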