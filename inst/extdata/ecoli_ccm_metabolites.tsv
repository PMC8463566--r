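metabolite_id	name	formula	is_currency
glc	D-glucose	C6H12O6	FALSE
fru	D-fructose	C6H12O6	FALSE
g6p	glucose 6-phosphate	C6H13O9P	FALSE
f6p	fructose 6-phosphate	C6H13O9P	FALSE
fbp	fructose 1,6-bisphosphate	C6H14O12P2	FALSE
dhap	dihydroxyacetone phosphate	C3H7O6P	FALSE
g3p	glyceraldehyde 3-phosphate	C3H7O6P	FALSE
bpg13	1,3-bisphosphoglycerate	C3H8O10P2	FALSE
pg3	3-phosphoglycerate	C3H7O7P	FALSE
pg2	2-phosphoglycerate	C3H7O7P	FALSE
pep	phosphoenolpyruvate	C3H5O6P	FALSE
pyr	pyruvate	C3H4O3	FALSE
accoa	acetyl-CoA	C23H38N7O17P3S	FALSE
actp	acetyl phosphate	C2H5O5P	FALSE
ac	acetate	C2H4O2	FALSE
lac	D-lactate	C3H6O3	FALSE
mgx	methylglyoxal	C3H4O2	FALSE
lgt	(R)-S-lactoylglutathione	C13H21N3O8S	FALSE
gsh	glutathione	C10H17N3O6S	FALSE
pgl	6-phosphogluconolactone	C6H11O9P	FALSE
pgc	6-phosphogluconate	C6H13O10P	FALSE
ru5p	ribulose 5-phosphate	C5H11O8P	FALSE
r5p	ribose 5-phosphate	C5H11O8P	FALSE
x5p	xylulose 5-phosphate	C5H11O8P	FALSE
s7p	sedoheptulose 7-phosphate	C7H15O10P	FALSE
e4p	erythrose 4-phosphate	C4H9O7P	FALSE
prpp	5-phosphoribosyl diphosphate	C5H13O14P3	FALSE
cit	citrate	C6H8O7	FALSE
acon	cis-aconitate	C6H6O6	FALSE
icit	isocitrate	C6H8O7	FALSE
akg	2-oxoglutarate	C5H6O5	FALSE
succoa	succinyl-CoA	C25H40N7O19P3S	FALSE
succ	succinate	C4H6O4	FALSE
fum	fumarate	C4H4O4	FALSE
mal	L-malate	C4H6O5	FALSE
oaa	oxaloacetate	C4H4O5	FALSE
glx	glyoxylate	C2H2O3	FALSE
glyc	glycerol	C3H8O3	FALSE
glyc3p	glycerol 3-phosphate	C3H9O6P	FALSE
glu	L-glutamate	C5H9NO4	FALSE
gln	L-glutamine	C5H10N2O3	FALSE
asp	L-aspartate	C4H7NO4	FALSE
ala	L-alanine	C3H7NO2	FALSE
atp	ATP	C10H16N5O13P3	TRUE
adp	ADP	C10H15N5O10P2	TRUE
amp	AMP	C10H14N5O7P	TRUE
nad	NAD+	C21H27N7O14P2	TRUE
nadh	NADH	C21H28N7O14P2	TRUE
nadp	NADP+	C21H28N7O17P3	TRUE
nadph	NADPH	C21H29N7O17P3	TRUE
coa	coenzyme A	C21H36N7O16P3S	TRUE
pi	orthophosphate	H3O4P	TRUE
ppi	diphosphate	H4O7P2	TRUE
h2o	water	H2O	TRUE
co2	carbon dioxide	CO2	TRUE
nh4	ammonia	NH3	TRUE
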