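vog	domain	order	family
VOG00001	Viruses	Caudovirales	Siphoviridae
VOG00002	Viruses	Caudovirales	Siphoviridae
VOG00003	Viruses	Caudovirales	Siphoviridae
VOG00004	Viruses	Caudovirales	Myoviridae
VOG00005	Viruses	Caudovirales	Myoviridae
VOG00006	Viruses	Caudovirales	Podoviridae
VOG00007	Viruses	Caudovirales	Podoviridae
VOG00008	Viruses	Petitvirales	Microviridae
VOG00009	Viruses	Petitvirales	Microviridae
VOG00010	Viruses	Caudovirales	Herelleviridae
VOG00011	Viruses	Tubulavirales	Inoviridae
VOG00012	Viruses	Caudovirales	NA
VOG00013	Viruses	NA	NA
VOG00014	Viruses	Caudovirales	Siphoviridae
VOG00015	Viruses	Caudovirales	Myoviridae
VOG00016	Viruses	Caudovirales	Podoviridae
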