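# Late-stage (phase III/IV) cardiovascular-trial drugs for the targets
# ADRA1A, PPARG and ROCK2: 15 drugs, 5 mechanisms of action, 13 disease
# indications, compiled from public drug-repurposing resources.
# The alias ADRA1A1 occasionally seen in summaries is normalized to the
# HGNC symbol ADRA1A.
# The drug-to-indication pairing below is a SYNTHETIC allocation: the
# source records list the 13 indications for the drug set as a whole, not
# per drug, so each drug was assigned clinically plausible indications
# from that list.
drug	target	mechanism	max_phase	indications
carvedilol	ADRA1A	adrenergic receptor antagonist	4	heart failure;hypertension;dilated cardiomyopathy;atrial fibrillation;cardiac arrhythmia
labetalol	ADRA1A	adrenergic receptor antagonist	4	hypertension;preeclampsia
doxazosin	ADRA1A	adrenergic receptor antagonist	4	hypertension
bunazosin	ADRA1A	adrenergic receptor antagonist	3	hypertension
terazosin	ADRA1A	adrenergic receptor antagonist	4	hypertension
midodrine	ADRA1A	adrenergic receptor agonist	4	hypotension
ephedrine	ADRA1A	adrenergic receptor agonist	4	hypotension
norepinephrine	ADRA1A	adrenergic receptor agonist	4	hypotension;cardiac arrest
phenylephrine	ADRA1A	adrenergic receptor agonist	4	hypotension
epinephrine	ADRA1A	adrenergic receptor agonist	4	cardiac arrest;acute coronary syndrome
droxidopa	ADRA1A	norepinephrine precursor	3	hypotension
bezafibrate	PPARG	PPAR receptor agonist	4	atherosclerosis;coronary artery disease
rosiglitazone	PPARG	PPAR receptor agonist	3	atherosclerosis;myocardial infarction
pioglitazone	PPARG	PPAR receptor agonist	4	myocardial ischemia;atherosclerosis
fasudil	ROCK2	Rho-associated kinase inhibitor	3	myocardial ischemia;coronary artery disease
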