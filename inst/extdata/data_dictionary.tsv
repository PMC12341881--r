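column	type	units	description
pig	character	-	unique pig identifier
batch	character	-	nursery batch (one company per batch)
company	character	-	breeding company of origin
pen	character	-	pen within batch
litter	character	-	full-sib litter (one dam per litter)
sire	character	-	sire identifier within batch
age	integer	days	age at entry into the quarantine nursery
storage_days	integer	days	days ground hair was stored before hormone extraction
hormone	character	-	assay target (cortisol, cortisone, dhea, dheas)
replicate	integer	-	assay replicate number within a sample
reading	numeric	pg/ml	raw ELISA reading of the reconstituted extract
rv	numeric	ml	reconstitution volume
em	numeric	mg	extraction mass of powdered hair
df	numeric	-	dilution factor applied before the assay
s_mean	numeric	pg/ml	replicate-policy mean assay reading
cv	numeric	fraction	within-sample replicate coefficient of variation
concentration	numeric	pg/mg	back-calculated hair concentration
high_cv	logical	-	within-sample CV above the flag threshold (retained)
cortisol	numeric	pg/mg	hair cortisol concentration
cortisone	numeric	pg/mg	hair cortisone concentration
dhea	numeric	pg/mg	hair DHEA concentration
dheas	numeric	pg/mg	hair DHEA-S concentration
sog	numeric	pg/mg	cortisol + cortisone
sod	numeric	pg/mg	DHEA + DHEA-S
ln_*	numeric	log pg/mg	natural log of the level or ratio named after the prefix
vn	integer	count	number of vocalizations during the 30-s backtest
sn	integer	count	number of struggles during the 30-s backtest
vi	integer	score 1-5	vocalization intensity
si	integer	score 1-5	struggle intensity
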