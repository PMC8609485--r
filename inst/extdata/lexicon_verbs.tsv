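l2	l1
write	schreiben
read	lesen
drink	trinken
eat	essen
see	sehen
buy	kaufen
find	finden
love	lieben
need	brauchen
make	machen
hold	halten
learn	lernen
play	spielen
cook	kochen
paint	malen
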