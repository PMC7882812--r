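# Per-dataset direction calls for the 17 consistently regulated neuronal
# guidance cue genes across three monocyte-to-macrophage differentiation
# datasets (mono_macro_rnaseq, mono_macro_microarray, thp1_microarray).
# call: Up / Down / - (not called); significant: asterisked in the source
# summary (P < 0.05 in that dataset), kept as metadata only.
gene	dataset_id	call	significant
NTNG2	mono_macro_rnaseq	Down	FALSE
NTNG2	mono_macro_microarray	Down	TRUE
NTNG2	thp1_microarray	-	FALSE
ADORA2B	mono_macro_rnaseq	Up	FALSE
ADORA2B	mono_macro_microarray	-	FALSE
ADORA2B	thp1_microarray	Up	TRUE
EPHA1	mono_macro_rnaseq	Down	FALSE
EPHA1	mono_macro_microarray	Down	TRUE
EPHA1	thp1_microarray	Down	TRUE
EPHB3	mono_macro_rnaseq	Down	FALSE
EPHB3	mono_macro_microarray	Down	TRUE
EPHB3	thp1_microarray	-	FALSE
EPHB4	mono_macro_rnaseq	Down	FALSE
EPHB4	mono_macro_microarray	Down	TRUE
EPHB4	thp1_microarray	Down	TRUE
SEMA3C	mono_macro_rnaseq	Up	FALSE
SEMA3C	mono_macro_microarray	-	FALSE
SEMA3C	thp1_microarray	Up	TRUE
SEMA4A	mono_macro_rnaseq	Down	FALSE
SEMA4A	mono_macro_microarray	Down	FALSE
SEMA4A	thp1_microarray	Down	FALSE
SEMA4B	mono_macro_rnaseq	Down	FALSE
SEMA4B	mono_macro_microarray	Down	TRUE
SEMA4B	thp1_microarray	-	FALSE
SEMA4D	mono_macro_rnaseq	Down	FALSE
SEMA4D	mono_macro_microarray	Down	TRUE
SEMA4D	thp1_microarray	Down	TRUE
SEMA4F	mono_macro_rnaseq	Up	FALSE
SEMA4F	mono_macro_microarray	Up	TRUE
SEMA4F	thp1_microarray	Up	TRUE
SEMA6A	mono_macro_rnaseq	Down	FALSE
SEMA6A	mono_macro_microarray	-	FALSE
SEMA6A	thp1_microarray	Down	TRUE
SEMA7A	mono_macro_rnaseq	Up	FALSE
SEMA7A	mono_macro_microarray	Up	TRUE
SEMA7A	thp1_microarray	Up	TRUE
NRP1	mono_macro_rnaseq	Up	FALSE
NRP1	mono_macro_microarray	Up	TRUE
NRP1	thp1_microarray	Up	TRUE
NRP2	mono_macro_rnaseq	Up	FALSE
NRP2	mono_macro_microarray	Up	TRUE
NRP2	thp1_microarray	Up	TRUE
PLXNA1	mono_macro_rnaseq	Up	FALSE
PLXNA1	mono_macro_microarray	Up	TRUE
PLXNA1	thp1_microarray	Up	TRUE
PLXNA3	mono_macro_rnaseq	Up	FALSE
PLXNA3	mono_macro_microarray	Up	TRUE
PLXNA3	thp1_microarray	Up	TRUE
PLXND1	mono_macro_rnaseq	-	FALSE
PLXND1	mono_macro_microarray	Up	TRUE
PLXND1	thp1_microarray	Up	TRUE
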