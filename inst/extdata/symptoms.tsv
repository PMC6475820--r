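# Demonstration symptom lexicon: concept_id<TAB>synonym, one per line.
# The concept id is implicitly its own synonym. Production analyses should
# substitute a full symptom synonym list in the same format.
steatorrhea	steatorrhea
steatorrhea	fatty stools
dyspepsia	dyspepsia
dyspepsia	indigestion
exophthalmos	exophthalmos
exophthalmos	bulging eyes
vomiting	vomiting
vomiting	throwing up
stomach ache	stomach ache
stomach ache	tummy ache
stomach ache	belly ache
diarrhea	diarrhea
diarrhea	loose stools
diarrhea	watery stools
xerostomia	xerostomia
xerostomia	dry mouth
flatulence	flatulence
flatulence	excess gas
abdominal pain	abdominal pain
abdominal pain	stomach pain
bloating	bloating
bloating	bloated
cough	cough
cough	coughing
headache	headache
headache	head ache
anxiety	anxiety
anxiety	anxious
bleeding	bleeding
bleeding	blood in stool
weight loss	weight loss
weight loss	losing weight
depression	depression
depression	feeling depressed
pain	pain
itch	itch
itch	itching
itch	itchy skin
fatigue	fatigue
fatigue	always tired
nausea	nausea
nausea	feeling sick
rash	rash
rash	skin rash
constipation	constipation
constipation	constipated
dizziness	dizziness
dizziness	dizzy
joint pain	joint pain
mouth ulcers	mouth ulcers
mouth ulcers	canker sores
hair loss	hair loss
tingling	tingling
tingling	pins and needles
insomnia	insomnia
insomnia	cant sleep
heartburn	heartburn
fever	fever
fever	high temperature
muscle cramps	muscle cramps
brain fog	brain fog
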