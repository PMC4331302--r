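# 22 synthetic 10-nt multiplex identifiers (MIDs), one per sample of a
# 22-sample design. These are stand-ins chosen for this package; the
# vendor MIDs used with the original assay were not published.
MID01	ACGAGTGCGT
MID02	ACGCTCGACA
MID03	AGACGCACTC
MID04	AGCACTGTAG
MID05	ATCAGACACG
MID06	ATATCGCGAG
MID07	CGTGTCTCTA
MID08	CTCGCGTGTC
MID09	TAGTATCAGC
MID10	TCTCTATGCG
MID11	TGATACGTCT
MID12	TACTGAGCTA
MID13	CATAGTAGTG
MID14	CGAGAGATAC
MID15	ATACGACGTA
MID16	TCACGTACTA
MID17	CGTCTAGTAC
MID18	TCTACGTAGC
MID19	TGTACTACTC
MID20	ACGACTACAG
MID21	CGTAGACTAG
MID22	TACGAGTATG
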