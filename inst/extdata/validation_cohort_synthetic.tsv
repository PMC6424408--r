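id	phenotype	genotype
DOG01	affected	hom_alt
DOG02	affected	hom_alt
DOG03	affected	hom_alt
DOG04	affected	hom_alt
DOG05	affected	hom_alt
DOG06	affected	hom_alt
DOG07	affected	hom_alt
DOG08	affected	hom_alt
DOG09	unaffected	het
DOG10	unaffected	het
DOG11	unaffected	het
DOG12	unaffected	het
DOG13	unaffected	het
DOG14	unaffected	het
DOG15	unaffected	het
DOG16	unaffected	het
DOG17	unaffected	het
DOG18	unaffected	hom_ref
DOG19	unaffected	hom_ref
DOG20	unaffected	hom_ref
DOG21	unaffected	hom_ref
DOG22	unaffected	hom_ref
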