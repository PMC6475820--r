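# Demonstration condition lexicon: concept_id<TAB>synonym, one per line.
lactose intolerance	lactose intolerance
inflammatory bowel disease	inflammatory bowel disease
inflammatory bowel disease	ibd
malabsorption	malabsorption
peptic ulcer	peptic ulcer
peptic ulcer	stomach ulcer
irritable bowel syndrome	irritable bowel syndrome
irritable bowel syndrome	ibs
food intolerance	food intolerance
crohn disease	crohn disease
crohn disease	crohns
crohn disease	crohn s disease
digestive disease	digestive disease
polycystic ovary syndrome	polycystic ovary syndrome
polycystic ovary syndrome	pcos
peritonitis	peritonitis
autoimmunity	autoimmunity
autoimmunity	autoimmune disease
attention deficit hyperactivity disorder	attention deficit hyperactivity disorder
attention deficit hyperactivity disorder	adhd
hypothyroidism	hypothyroidism
hypothyroidism	underactive thyroid
gastroesophageal reflux disease	gastroesophageal reflux disease
gastroesophageal reflux disease	gerd
gastroesophageal reflux disease	acid reflux
asthma	asthma
influenza	influenza
influenza	flu
migraine	migraine
migraine	migraines
colitis	colitis
colitis	microscopic colitis
systemic lupus erythematosus	systemic lupus erythematosus
systemic lupus erythematosus	lupus
alzheimer disease	alzheimer disease
alzheimer disease	alzheimers
anemia	anemia
osteoporosis	osteoporosis
type 1 diabetes	type 1 diabetes
eczema	eczema
psoriasis	psoriasis
dermatitis herpetiformis	dermatitis herpetiformis
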