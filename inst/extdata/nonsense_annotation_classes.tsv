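# Annotation-class composition of nonsense mutations vs. all ORFs in the
# eighteen-strain N. crassa panel; classes other than conserved-hypothetical
# are pooled because only the aggregate is tabulated.
class	n_nonsense	n_genes
conserved_hypothetical	313	6481
other	92	3253
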