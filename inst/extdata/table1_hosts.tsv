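# Host species, Wolbachia strain annotations and phage WO type counts
# for the 19 Wolbachia-infected butterfly species of the survey.
# strain_st "-" = no data obtained (MLST loci failed to amplify).
species	family	strain_st	wsp_allele	supergroup	n_types
Isoteinon sp.	Hesperiidae	ST-41	wsp-10	B	9
Notocrypta sp.	Hesperiidae	ST-41	wsp-10	B	8
Ochlodes thibetana	Hesperiidae	ST-374	wsp-64	B	5
Pseudozizeeria maha	Lycaenidae	ST-41	wsp-10	B	17
Ariadne ariadne	Nymphalidae	ST-41	wsp-10	B	3
Junonia almana	Nymphalidae	ST-125	wsp-10	B	8
Limenitis doerriesi	Nymphalidae	ST-297	wsp-61	B	1
Mycalesis francisca	Nymphalidae	-	wsp-10	B	9
Polygonia c-aureum	Nymphalidae	ST-wPcau	wsp-266	B	1
Stichophthalma sp.	Nymphalidae	ST-374	wsp-64	B	2
Vanessa indica	Nymphalidae	ST-125	wsp-10	B	8
Ypthima praenubila	Nymphalidae	ST-19	wsp-108	A	10
Ypthima sp.	Nymphalidae	ST-19	wsp-108	A	6
Parnassius stubbendorfii	Papilionidae	-	wsp-369	B	7
Colias croceus	Pieridae	ST-141	wsp-61	B	8
Delias agostina	Pieridae	-	wsp-10	B	7
Eurema blanda	Pieridae	ST-41	wsp-10	B	8
Eurema hecabe	Pieridae	ST-41	wsp-10	B	5
Leptosia nina	Pieridae	ST-41	wsp-10	B	4
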