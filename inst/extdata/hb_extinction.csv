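# Molar extinction coefficients of human hemoglobin (cm^-1 / M) at the two
# PAM excitation wavelengths used for sO2 imaging.
# Source: compiled from the Gratzer/Kollias whole-blood tabulation as
# distributed by the Oregon Medical Laser Center (omlc.org), version of the
# widely mirrored "Optical absorption of hemoglobin" table.
# Columns: wavelength_nm, eps_hbo2 (oxyhemoglobin), eps_hb (deoxyhemoglobin)
wavelength_nm,eps_hbo2,eps_hb
532,44480,41304
559,31620,53412
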