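# Per-tissue functional parameter ranges sampled uniformly per phantom.
# so2 ranges: arteries strictly above veins by construction.
# blood/water/fat volume fractions sum to <= 1 in every tissue.
# version: 1
label,so2_lo,so2_hi,blood_vf,water_vf,fat_vf
water,0.0,0.0,0.00,1.00,0.00
epidermis,0.70,0.80,0.002,0.60,0.10
dermis,0.70,0.80,0.02,0.60,0.10
fat,0.70,0.80,0.01,0.15,0.75
fibroglandular,0.70,0.80,0.02,0.50,0.20
artery,0.92,0.98,1.00,0.00,0.00
vein,0.60,0.75,1.00,0.00,0.00
tumor_viable,0.55,0.75,0.05,0.60,0.10
tumor_necrotic,0.10,0.30,0.005,0.60,0.10
tumor_angiogenesis,0.55,0.75,0.04,0.60,0.10
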