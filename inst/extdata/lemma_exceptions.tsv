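inflected	base
children	child
women	woman
men	man
mice	mouse
feet	foot
teeth	tooth
geese	goose
criteria	criterion
phenomena	phenomenon
bacteria	bacterium
data	data
media	media
analyses	analysis
diagnoses	diagnosis
hypotheses	hypothesis
metastases	metastasis
prognoses	prognosis
apoptoses	apoptosis
carcinomas	carcinoma
species	species
series	series
higher	high
highest	high
lower	low
lowest	low
larger	large
largest	large
smaller	small
smallest	small
greater	great
greatest	great
better	good
best	good
worse	bad
worst	bad
older	old
oldest	old
younger	young
youngest	young
stronger	strong
strongest	strong
weaker	weak
weakest	weak
earlier	early
earliest	early
longer	long
longest	long
shorter	short
shortest	short
fewer	few
wider	wide
widest	wide
deeper	deep
deepest	deep
faster	fast
fastest	fast
slower	slow
slowest	slow
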