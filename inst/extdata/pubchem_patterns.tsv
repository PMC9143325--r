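# SMARTS catalog for the pattern sections (bits 328-881) of the 881-bit
# public-layout substructure-key fingerprint. Columns: bit, smarts, label.
# Bits without an entry are always 0. Replace this file (or pass
# catalog_path) to supply a fuller or official bit-indexed catalog.
bit	smarts	label
328	[CX4H3]	methyl
329	[CX4H2]	methylene
330	[CX4H1]	methine
331	[CX4H0]	quaternary_carbon
332	C=C	alkene
333	C#C	alkyne
334	[#6]~[#7]	carbon_nitrogen
335	C=N	imine
336	C#N	nitrile
337	[#6]~[#8]	carbon_oxygen
338	C=O	carbonyl
339	[#6]~[#16]	carbon_sulfur
340	C=S	thiocarbonyl
341	[#6]F	carbon_fluorine
342	[#6]Cl	carbon_chlorine
343	[#6]Br	carbon_bromine
344	[#6]I	carbon_iodine
345	[#7]~[#7]	nitrogen_nitrogen
346	N=N	azo
347	[#7]~[#8]	nitrogen_oxygen
348	N=O	nitroso_or_nitro
349	[#7]~[#16]	nitrogen_sulfur
350	[#8]~[#16]	oxygen_sulfur
351	S=O	sulfoxide_like
352	[#8]~[#15]	oxygen_phosphorus
353	P=O	phosphoryl
354	[OX2H]	hydroxyl
355	[NX3;H2]	primary_amine
356	[NX3;H1]	secondary_amine
357	[NX3;H0;!$(N=*)]	tertiary_amine
358	[SX2H]	thiol
359	[#6][OX2][#6]	ether
360	[#6][SX2][#6]	thioether
361	[CX3](=O)[#6]	ketone_or_acyl
362	[CX3H1]=O	aldehyde
363	[CX3](=O)[OX2H1]	carboxylic_acid
364	[CX3](=O)[OX2][#6]	ester
365	[CX3](=O)[NX3]	amide
366	[NX3][CX3](=O)[NX3]	urea
367	[OX2][CX3](=O)[NX3]	carbamate
368	[NX3][CX3](=[NX2])[NX3]	guanidine
369	[NX2]=[CX3][NX3]	amidine
370	[N+](=O)[O-]	nitro
371	[#16](=O)(=O)	sulfonyl
372	[#16](=O)(=O)[NX3]	sulfonamide
373	[#16](=O)(=O)[OX2]	sulfonate
374	[PX4](=O)([OX2])[OX2]	phosphate_ester
375	[F,Cl,Br,I]	halogen
376	[N+]	positively_charged_nitrogen
377	[O-]	negatively_charged_oxygen
378	[#6]~[#6]~[#6]	c3_chain
379	[#6]~[#6]~[#6]~[#6]	c4_chain
380	[#6]~[#6]~[#7]	cc_n
381	[#6]~[#7]~[#6]	cnc
382	[#6]~[#8]~[#6]	coc
383	[#7]~[#6]~[#7]	ncn
384	[#8]~[#6]~[#8]	oco
385	[#6]~[#6]=O	cc_carbonyl
386	O=[#6]~[#6]=O	dicarbonyl
387	[#6]=[#6]-[#6]=[#6]	conjugated_diene
388	[#6]=[#6]-[#6]=O	enone
389	[OX2H][#6]~[#6][OX2H]	diol_vicinal
390	[NX3][#6]~[#6][NX3]	diamine_vicinal
391	[OX2H][CX4][CX3]=O	alpha_hydroxy_carbonyl
392	[NX3][CX4][CX3]=O	alpha_amino_carbonyl
393	[#6](~[#6])(~[#6])~[#6]	branched_carbon
394	[#6](~[#6])(~[#6])(~[#6])~[#6]	quaternary_center
395	[#6](~[#7])~[#8]	n_c_o_center
396	[#6](~[#8])~[#8]	o_c_o_center
397	[#6](~[#7])~[#7]	n_c_n_center
398	[#6](~[#16])~[#7]	s_c_n_center
399	[CX4][OX2H]	aliphatic_alcohol
400	[CX4][NX3]	aliphatic_amine
401	[CX4]F	aliphatic_fluoride
402	[CX4]Cl	aliphatic_chloride
403	C(F)(F)F	trifluoromethyl
404	[#6]=[#6][F,Cl,Br,I]	vinyl_halide
405	[CX3](=O)[F,Cl,Br,I]	acyl_halide
406	[#7][CX4][#7]	aminal
407	[#8][CX4][#8]	acetal
408	[#6]#[#6][#6]	internal_alkyne
409	[#7]~[#7]~[#6]	nnc
410	[#7]=[#7+]=[#7-]	azide
411	[NX3][NX3]	hydrazine
412	[NX3][OX2H]	hydroxylamine
413	[#6][Si]	organosilicon
414	[#6][Se]	organoselenium
415	[#6]~[#15]	carbon_phosphorus
460	c1ccccc1	benzene
461	c1ccncc1	pyridine
462	c1ccc2ccccc2c1	naphthalene
463	[cH0]	substituted_aromatic_carbon
464	c[OX2H]	phenol
465	c[NX3;H2,H1]	aniline_like
466	c[NX3]	aromatic_amine_any
467	cF	aryl_fluoride
468	cCl	aryl_chloride
469	cBr	aryl_bromide
470	cI	aryl_iodide
471	c[CX4]	alkyl_aryl
472	c[CX3]=O	aryl_carbonyl
473	c[CX3](=O)[OX2H1]	aryl_carboxylic_acid
474	c[CX3](=O)[NX3]	aryl_amide_c
475	c[NX3][CX3]=O	anilide
476	c[N+](=O)[O-]	nitroaromatic
477	c[OX2][#6]	aryl_ether
478	c[SX2]	aryl_thioether
479	c[#16](=O)(=O)	aryl_sulfonyl
480	c[CX2]#N	aryl_nitrile
481	cc[OX2H]	ortho_reachable_phenol
482	c1ccc(cc1)[OX2H]	para_phenol_axis
483	c-,:c-,:c	aromatic_chain3
484	c1ccc2c(c1)cccc2[OX2H]	naphthol_like
485	[c][CX4][c]	diarylmethane
486	c~n~c	aromatic_ncn_path
487	[nX2]	pyridine_type_n
488	[nX3H1]	pyrrole_type_nh
489	[o]	aromatic_oxygen
490	[s]	aromatic_sulfur
491	c1cc[nH]c1	pyrrole
492	c1ccoc1	furan
493	c1ccsc1	thiophene
494	c1cnc[nH]1	imidazole
495	c1cn[nH]c1	pyrazole
496	c1cscn1	thiazole
497	c1cocn1	oxazole
498	c1cnccn1	pyrazine
499	c1ccncn1	pyrimidine
500	c1ccnnc1	pyridazine
501	c1cnn[cH]1	pyrazole_tautomer
502	c1nnc[nH]1	triazole
503	c1nnnn1	tetrazole_any
504	c1ccc2[nH]ccc2c1	indole
505	c1ccc2ncccc2c1	quinoline_like
506	c1ccc2[nH]cnc2c1	benzimidazole
507	c1ccc2occc2c1	benzofuran
508	c1ccc2sccc2c1	benzothiophene
509	c1ccc2nccnc2c1	quinoxaline
510	c1ccc2c(c1)ncn2	benzimidazole_alt
511	c1ncc2nc[nH]c2n1	purine
512	C1CC1	cyclopropane
513	C1CCC1	cyclobutane
514	C1CCCC1	cyclopentane
515	C1CCCCC1	cyclohexane
516	C1CCCCCC1	cycloheptane
517	C1CCNCC1	piperidine
518	C1CNCCN1	piperazine
519	C1CCOCC1	tetrahydropyran
520	C1CCSCC1	thiane
521	C1COCCN1	morpholine
522	C1CCNC1	pyrrolidine
523	C1CCOC1	tetrahydrofuran
524	C1CO1	epoxide
525	C1CN1	aziridine
526	O=C1CCN1	beta_lactam
527	O=C1CCCN1	gamma_lactam
528	O=C1CCCCN1	delta_lactam
529	O=C1CCO1	beta_lactone_like
530	O=C1CCCO1	gamma_lactone
531	O=C1CCC(=O)N1	imide_ring
532	[CX4]1[CX4][CX4][CX4][CX4][CX4]1[OX2H]	cyclohexanol_like
533	C1CCC2CCCCC2C1	decalin_like
534	C1CC2CCC1C2	bicyclic_bridged
535	[#6]1~[#6]~[#6]~[#6]~[#6]~[#6]1~[#7]	ring6_attached_n
536	[#6]1~[#6]~[#6]~[#6]~[#6]~[#6]1~[#8]	ring6_attached_o
537	[R2]	ring_fusion_atom
538	[R;!c]	aliphatic_ring_atom
539	[NX3;R][CX3](=O)	cyclic_amide_n
540	[OX2;R][CX3](=O)	cyclic_ester_o
541	[#7;R]1[#6;R][#6;R][#7;R][#6;R][#6;R]1	ring_dinitrogen6
542	c1ccc(cc1)c1ccccc1	biphenyl
543	c1ccc(cc1)O[#6]	aryl_alkyl_ether
544	c1ccc(cc1)N	aryl_n_substituent
545	c1ccc(cc1)S	aryl_s_substituent
546	c1ccc(cc1)[CX3](=O)[OX2][#6]	aryl_ester
547	[#6]=[#6]c1ccccc1	styrene_like
548	O=C(c1ccccc1)c1ccccc1	benzophenone_like
549	c1ccc(cc1)C(F)(F)F	aryl_cf3
550	[OX2H][CX4][CX4][NX3]	aminoalcohol
551	[CX4]([OX2H])([#6])[#6]	secondary_alcohol
552	[CX4]([OX2H])([#6])([#6])[#6]	tertiary_alcohol
553	[CX3](=O)[OX2][CX3](=O)	anhydride
554	[NX2]=[CX3]	schiff_base
555	[#6][NX2]=[OX1]	c_nitroso
556	[OX2][NX2]=O	nitrite_like
557	[#7+][O-]	n_oxide
558	[S;D2]([#6])[S;D2]	disulfide_path
559	[#16]~[#16]	sulfur_sulfur
560	[PX3]	trivalent_phosphorus
561	[#15]~[#7]	phosphorus_nitrogen
562	[B]	boron_any
563	[#6]=[#6]([#6])[#6]	trisubstituted_alkene
564	[CX4]([F,Cl,Br,I])([F,Cl,Br,I])	geminal_dihalide
565	[#8]=[#6]([#7])[#7]	urea_core
566	[#6]1[#6][#6][#6][#6][#6][#6]1	ring7_any
567	[r8]	ring8_atom
568	[r3]	ring3_atom
569	[r4]	ring4_atom
570	[r5]	ring5_atom
571	[r6]	ring6_atom
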