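# perturbr bundled sounds-like dictionary, version 1
# word<TAB>pipe-separated candidates, ordered by preference
ate	eight
aural	oral
blew	blue
blue	blew
board	bored
bored	board
cell	sell
cereal	serial
chord	cord
cite	site|sight
cord	chord
did	deed
die	dye
dye	die
eight	ate
feat	feet
feet	feat
flew	flu
flour	flower
flower	flour
flu	flew
for	four
four	for
grate	great
great	grate
heal	heel
hear	here
heel	heal
here	hear
hoarse	horse
hole	whole
horse	hoarse
hour	our
in	inn
knee	nee
knight	night
knows	nose
mail	male
male	mail
muscle	mussel
mussel	muscle
night	knight
nose	knows
one	won
oral	aural
our	hour
pail	pale
pain	pane
pale	pail
pane	pain
plain	plane
plane	plain
rest	wrest
right	write|rite
role	roll
roll	role
sell	cell
serial	cereal
sight	site|cite
site	sight|cite
soar	sore
sole	soul
son	sun
sore	soar
soul	sole
steal	steel
steel	steal
sun	son
tide	tied
tied	tide
to	too|two
too	two
two	too
vain	vein|vane
vane	vein|vain
vein	vane|vain
waist	waste
wait	weight
waste	waist
weak	week
week	weak
weight	wait
whole	hole
won	one
wrest	rest
write	right|rite
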