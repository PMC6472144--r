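{
  "posemo": ["heureux", "joie", "merci", "bonheur", "sourire", "espoir", "formidable", "magnifique", "super", "courage", "content*", "fier*"],
  "sadness": ["chagrin", "deuil", "douleur", "perdu", "triste*", "pleur*", "larme*"],
  "anxiety": ["peur", "anxieux", "terreur", "effroi", "panique", "angoisse*", "inquiet*"],
  "anger": ["colère", "rage", "furieux", "haine", "énervé", "scandale", "indign*"],
  "negemo": ["chagrin", "deuil", "douleur", "perdu", "peur", "anxieux", "terreur", "effroi", "panique", "colère", "rage", "furieux", "haine", "énervé", "scandale", "horrible", "terrible", "mal", "triste*", "pleur*", "larme*", "angoisse*", "inquiet*", "indign*"],
  "social": ["famille", "ensemble", "parler", "gens", "communauté", "ami*", "frère*", "soeur*", "voisin*", "discut*", "rencontre*", "partag*"],
  "prosocial": ["entraide", "aider", "généreux", "ong", "solidar*", "soutien*", "don*", "bénévol*", "secour*", "accueil*"],
  "values": ["république", "démocratie", "laïcité", "valeurs", "liberté*", "égalité*", "fraternité*", "citoyen*"],
  "i": ["je", "j'ai", "moi", "mon", "ma", "mes", "me"],
  "attack": ["fusillade", "explosion", "assaut", "attentat*", "attaque*", "terroris*", "otage*"]
}
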