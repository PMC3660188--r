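# Primer pair amplifying the SRY coding exon (824 bp product; the coding
# region runs from position 89 to 703 of the amplicon, 615 bp).
id	seq	length	start	end	orientation
SA531	GAATCTGGTAGAAGTGAGTTTTGGA	25	61	85	forward
SA532	GCCTTTATTAGCCAGAGAAAAGAAA	25	860	884	reverse
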