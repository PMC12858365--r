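# Chromophore specific absorption at the three excitation wavelengths.
# HbO2/Hb: mm^-1 per mM of heme (molar extinction from the standard Prahl
#   compilation, converted by ln(10) * 1e-4).
# water/fat: mm^-1 per unit volume fraction (Hale & Querry water; van Veen lipid).
# melanin: interior-melanosome absorption, mm^-1 per unit melanosome volume
#   fraction (Jacques 519*(lambda/500)^-3.48 cm^-1 model).
# version: 1
name,wavelength_nm,epsilon,units
HbO2,757,0.13127,mm-1.per.mM
HbO2,800,0.18792,mm-1.per.mM
HbO2,850,0.24366,mm-1.per.mM
Hb,757,0.37309,mm-1.per.mM
Hb,800,0.17549,mm-1.per.mM
Hb,850,0.15914,mm-1.per.mM
water,757,0.00272,mm-1.per.vf
water,800,0.00204,mm-1.per.vf
water,850,0.00433,mm-1.per.vf
fat,757,0.00050,mm-1.per.vf
fat,800,0.00070,mm-1.per.vf
fat,850,0.00080,mm-1.per.vf
melanin,757,12.20,mm-1.per.vf
melanin,800,10.10,mm-1.per.vf
melanin,850,8.20,mm-1.per.vf
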