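# Literature-informed per-tissue baseline properties.
# musp800: reduced scattering coefficient at 800 nm, mm^-1 (mus' = musp800*(lambda/800)^-bmie)
# g: scattering anisotropy; n: refractive index
# c: sound speed m/s; rho: density kg/m^3
# alpha0: acoustic attenuation dB MHz^-y cm^-1; ypow: power-law exponent
# version: 1
label,musp800,bmie,g,n,c,rho,alpha0,ypow
water,0.0005,1.0,0.90,1.33,1480,1000,0.0022,2.0
epidermis,2.00,1.0,0.85,1.40,1610,1109,1.00,1.1
dermis,2.00,1.0,0.85,1.40,1610,1109,1.00,1.1
fat,0.95,0.7,0.90,1.40,1440,911,0.38,1.1
fibroglandular,1.20,1.0,0.90,1.40,1515,1041,0.75,1.1
artery,0.75,1.0,0.95,1.40,1575,1050,0.21,1.2
vein,0.75,1.0,0.95,1.40,1575,1050,0.21,1.2
tumor_viable,1.10,1.0,0.90,1.40,1560,1050,0.75,1.1
tumor_necrotic,1.00,1.0,0.90,1.40,1560,1050,0.75,1.1
tumor_angiogenesis,1.10,1.0,0.90,1.40,1560,1050,0.75,1.1
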