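l2	l1
book	Buch
house	Haus
girl	Maedchen
man	Mann
woman	Frau
child	Kind
dog	Hund
cat	Katze
apple	Apfel
bread	Brot
water	Wasser
potato	Kartoffel
letter	Brief
car	Auto
garden	Garten
teacher	Lehrer
friend	Freund
school	Schule
table	Tisch
window	Fenster
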