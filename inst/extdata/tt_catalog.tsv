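# Default curated catalog of transcription- and translation-machinery genes.
# One row per canonical gene; multi-valued fields are semicolon-joined.
# Function keywords are matched case-insensitively on word boundaries against
# annotation product strings. Dual-role coupling factors (nusA, nusG) are
# filed under transcription; cassette-level "both" status arises from the
# mixture of categories within a cassette.
canonical_gene	category	synonyms	function_keywords	cog_ids
rpoA	transcription		dna-directed rna polymerase subunit alpha	COG0202K
rpoB	transcription		dna-directed rna polymerase subunit beta	COG0085K
nusA	transcription		transcription elongation factor nusa	COG0195K
nusG	transcription		transcription termination factor;transcription antitermination protein nusg	COG0250K
mfd	transcription		transcription-repair coupling factor	COG1197LK
ylxR	translation		nucleoid-associated protein ylxr	COG2740K
rplQ	translation		50s ribosomal protein l17	COG0203J
rpsM	translation		30s ribosomal protein s13	COG0099J
rpsK	translation		30s ribosomal protein s11	COG0100J
rpsD	translation		30s ribosomal protein s4	COG0522J
infB	translation		translation initiation factor if-2	COG0532J
rplK	translation		50s ribosomal protein l11	COG0080J
rplA	translation		50s ribosomal protein l1	COG0081J
rimP	translation	yhbC	ribosome maturation factor rimp	COG0779S
rbfA	translation		ribosome-binding factor a	COG0858J
rpmJ	translation		50s ribosomal protein l36	COG0257J
secE	translation		preprotein translocase subunit sece	COG0690U
secY	translation		preprotein translocase subunit secy	COG0201U
rplO	translation		50s ribosomal protein l15	COG0200J
rplR	translation		50s ribosomal protein l18	COG0256J
rpsE	translation		30s ribosomal protein s5	COG0098J
rpsH	translation		30s ribosomal protein s8	COG0096J
truB	translation		trna pseudouridine synthase b	COG0130J
infA	translation		translation initiation factor if-1	COG0361J
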