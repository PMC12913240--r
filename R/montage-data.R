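# 64-channel montage for the 10-20/10-10 system, with adjacency and nested
# reduced caps. Positions are idealized unit-sphere electrode coordinates
# (x right, y front, z up).

.montage64_labels <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "M1", "M2", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8", "O1", "Oz", "O2")
.montage64_x <- c(-0.329991, 0.001272, 0.330899, -0.620076, -0.389395, 0.404395, 0.620326, -0.847627, -0.784679, -0.595220, -0.314606, 0.003526, 0.335604, 0.606623, 0.791456, 0.846108, -0.976104, -0.929019, -0.708119, -0.375357, 0.004053, 0.386023, 0.717488, 0.929583, 0.973730, -0.976571, -0.927952, -0.706876, -0.371708, 0.003983, 0.390044, 0.720988, 0.934162, 0.978884, -0.726044, 0.724712, -0.876639, -0.818335, -0.618606, -0.326425, 0.003504, 0.351645, 0.637648, 0.831488, 0.880320, -0.701950, -0.637048, -0.480960, -0.251075, 0.002804, 0.275926, 0.498504, 0.642647, 0.706832, -0.489979, -0.430035, -0.321642, 0.001891, 0.324496, 0.439599, 0.495193, -0.252329, 0.000929, 0.256398)
.montage64_y <- c(0.940726, 0.999811, 0.940402, 0.775350, 0.887815, 0.880143, 0.775159, 0.512395, 0.584687, 0.629189, 0.651404, 0.660786, 0.654987, 0.635512, 0.580704, 0.514567, 0.170633, 0.224309, 0.267286, 0.286639, 0.295142, 0.293400, 0.273238, 0.233006, 0.183483, -0.185874, -0.159047, -0.125802, -0.102635, -0.091066, -0.099645, -0.117092, -0.143011, -0.172815, -0.379484, -0.380199, -0.475591, -0.478616, -0.457546, -0.434692, -0.429705, -0.431251, -0.446439, -0.460056, -0.468673, -0.711819, -0.722449, -0.714878, -0.706414, -0.700597, -0.695760, -0.703519, -0.718535, -0.706954, -0.871377, -0.882201, -0.888450, -0.896107, -0.889716, -0.877495, -0.868443, -0.964666, -0.991960, -0.963610)
.montage64_z <- c(-0.078359, -0.019408, -0.078426, -0.119742, 0.245268, 0.248623, -0.119684, -0.137767, 0.205963, 0.499834, 0.690432, 0.750566, 0.677025, 0.477633, 0.190737, -0.139004, -0.134558, 0.294293, 0.653548, 0.881445, 0.955445, 0.874587, 0.640743, 0.285628, -0.134845, -0.108447, 0.337058, 0.696060, 0.922659, 0.995837, 0.915389, 0.682983, 0.326939, -0.109187, -0.573456, -0.574666, -0.072917, 0.318205, 0.638732, 0.839339, 0.902963, 0.830884, 0.627771, 0.311412, -0.073370, -0.024101, 0.268769, 0.507570, 0.661771, 0.713552, 0.663161, 0.506513, 0.265919, -0.024575, 0.024946, 0.191811, 0.327418, 0.443835, 0.321103, 0.191715, 0.024285, 0.075827, 0.126546, 0.075607)
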