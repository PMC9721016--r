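name	abbreviation	bonds	solubility
Inulin	Inu	b2-1:Fru-Fru;b1-2:Glc-Fru	soluble
Levan	Lev	b2-6:Fru-Fru;b1-2:Glc-Fru	soluble
Beta-glucan	BG	b1-3:Glc-Glc;b1-4:Glc-Glc	soluble
Cellulose	Cel	b1-4:Glc-Glc	insoluble
Xylan	Xyl	b1-4:Xyl-Xyl	insoluble
Glucomannan	GluM	b1-4:Man-Man;b1-4:Glc-Man	soluble
Galactomannan	GalM	b1-4:Man-Man;a1-6:Gal-Man	soluble
Mannan	Man	b1-4:Man-Man	insoluble
Arabinoxylan	AX	b1-4:Xyl-Xyl;a1-2:Ara-Xyl;a1-3:Ara-Xyl	soluble
Galactan	Gal	b1-4:Gal-Gal	soluble
Arabinan	Ara	a1-5:Ara-Ara;a1-3:Ara-Ara;a1-2:Ara-Ara	soluble
Arabinogalactan	AG	b1-3:Gal-Gal;b1-6:Gal-Gal;a1-3:Ara-Gal	soluble
Dextran	Dex	a1-6:Glc-Glc;a1-3:Glc-Glc	soluble
Chitin	Chi	b1-4:GlcNAc-GlcNAc	insoluble
Rhamnogalacturonan	RH	a1-2:Rha-GalA;a1-4:GalA-Rha	soluble
Pectin	Pec	a1-4:GalA-GalA	soluble
Carrageenan	Car	b1-4:Gal-AnGal;a1-3:AnGal-Gal	soluble
Galactoglucomannan	GalGluM	b1-4:Man-Man;b1-4:Glc-Man;a1-6:Gal-Man	soluble
Alginate	Alg	b1-4:ManA-ManA;a1-4:GulA-GulA;b1-4:ManA-GulA	soluble
Xanthan	Xan	b1-4:Glc-Glc;a1-3:Man-Glc;b1-2:GlcA-Man	soluble
Xyloglucan	XG	b1-4:Glc-Glc;a1-6:Xyl-Glc	insoluble
Laminaran	Lam	b1-3:Glc-Glc;b1-6:Glc-Glc	soluble
Gellan	Gel	b1-4:Glc-GlcA;b1-4:GlcA-Glc;b1-4:Glc-Rha;a1-3:Rha-Glc	soluble
Resistant starch	RS	a1-4:Glc-Glc;a1-6:Glc-Glc	insoluble
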