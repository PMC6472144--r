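%
1	posemo
2	sadness
3	anxiety
4	anger
5	negemo
6	social
7	prosocial
8	values
9	i
10	attack
%
heureux	1
joie	1
merci	1
bonheur	1
sourire	1
espoir	1
formidable	1
magnifique	1
super	1
courage	1
content*	1
fier*	1
chagrin	2	5
deuil	2	5
douleur	2	5
perdu	2	5
triste*	2	5
pleur*	2	5
larme*	2	5
peur	3	5
anxieux	3	5
terreur	3	5
effroi	3	5
panique	3	5
angoisse*	3	5
inquiet*	3	5
colère	4	5
rage	4	5
furieux	4	5
haine	4	5
énervé	4	5
scandale	4	5
indign*	4	5
horrible	5
terrible	5
mal	5
famille	6
ensemble	6
parler	6
gens	6
communauté	6
ami*	6
frère*	6
soeur*	6
voisin*	6
discut*	6
rencontre*	6
partag*	6
entraide	7
aider	7
généreux	7
ong	7
solidar*	7
soutien*	7
don*	7
bénévol*	7
secour*	7
accueil*	7
république	8
démocratie	8
laïcité	8
valeurs	8
liberté*	8
égalité*	8
fraternité*	8
citoyen*	8
je	9
j'ai	9
moi	9
mon	9
ma	9
mes	9
me	9
fusillade	10
explosion	10
assaut	10
attentat*	10
attaque*	10
terroris*	10
otage*	10
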