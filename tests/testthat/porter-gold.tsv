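seizures	seizur
seizure	seizur
dizziness	dizzi
drowsiness	drowsi
headaches	headach
nausea	nausea
vomiting	vomit
constipation	constip
sweating	sweat
sleeplessness	sleepless
restlessness	restless
nervousness	nervous
hallucinations	hallucin
tremors	tremor
pruritus	pruritu
itching	itch
flushing	flush
bleeding	bleed
ulcers	ulcer
palpitations	palpit
agitation	agit
insomnia	insomnia
fatigue	fatigu
weakness	weak
rashes	rash
swelling	swell
drowsy	drowsi
sleepy	sleepi
anxious	anxiou
anxiety	anxieti
depression	depress
depressive	depress
suicidal	suicid
ideation	ideat
confusion	confus
confused	confus
dryness	dryness
tingling	tingl
numbness	numb
cramping	cramp
cramps	cramp
stiffness	stiff
soreness	sore
aching	ach
aches	ach
pains	pain
painful	pain
tiredness	tired
irritability	irrit
irritated	irrit
inflammation	inflamm
inflamed	inflam
infections	infect
infectious	infecti
allergies	allergi
allergic	allerg
reactions	reaction
reacting	react
reported	report
reporting	report
association	associ
associations	associ
abnormalities	abnorm
abnormal	abnorm
administration	administr
administered	administ
medication	medic
medications	medic
prescriptions	prescript
prescribed	prescrib
dosages	dosag
overdose	overdos
toxicity	toxic
toxicological	toxicolog
monitoring	monitor
monitored	monitor
observations	observ
observed	observ
computations	comput
computed	comput
generalizations	gener
oscillators	oscil
relational	relat
conditional	condit
rational	ration
troubled	troubl
hopping	hop
agreed	agre
caresses	caress
ponies	poni
controlled	control
rolling	roll
sensitiviti	sensit
formalize	formal
electrical	electr
adjustable	adjust
replacement	replac
dependent	depend
activated	activ
probated	probat
vomited	vomit
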