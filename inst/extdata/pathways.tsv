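pathway	name
map00010	Glycolysis / Gluconeogenesis
map00020	Citrate cycle (TCA cycle)
map00030	Pentose phosphate pathway
map00040	Pentose and glucuronate interconversions
map00051	Fructose and mannose metabolism
map00052	Galactose metabolism
map00053	Ascorbate and aldarate metabolism
map00061	Fatty acid biosynthesis
map00190	Oxidative phosphorylation
map00230	Purine metabolism
map00240	Pyrimidine metabolism
map00250	Alanine, aspartate and glutamate metabolism
map00260	Glycine, serine and threonine metabolism
map00270	Cysteine and methionine metabolism
map00280	Valine, leucine and isoleucine degradation
map00310	Lysine degradation
map00330	Arginine and proline metabolism
map00340	Histidine metabolism
map00350	Tyrosine metabolism
map00360	Phenylalanine metabolism
map00380	Tryptophan metabolism
map00430	Taurine and hypotaurine metabolism
map00480	Glutathione metabolism
map00500	Starch and sucrose metabolism
map00520	Amino sugar and nucleotide sugar metabolism
map00561	Glycerolipid metabolism
map00562	Inositol phosphate metabolism
map00564	Glycerophospholipid metabolism
map00590	Arachidonic acid metabolism
map00591	Linoleic acid metabolism
map00600	Sphingolipid metabolism
map00740	Riboflavin metabolism
map00750	Vitamin B6 metabolism
map00760	Nicotinate and nicotinamide metabolism
map00770	Pantothenate and CoA biosynthesis
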