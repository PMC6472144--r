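# Synthetic demo lexicon pack. The genuine French LIWC dictionary is
# licensed material and is never bundled; these small category lists
# exist so that the scoring pipeline, the generators and the tests have
# a concrete dictionary to run against. Word choice is plausible French
# but the lists are deliberately tiny and NOT a validated instrument.

.demo_words <- list(
  posemo = c("heureux", "content*", "joie", "merci", "bonheur", "sourire",
             "espoir", "fier*", "formidable", "magnifique", "super",
             "courage"),
  sadness = c("triste*", "chagrin", "pleur*", "larme*", "deuil",
              "douleur", "perdu"),
  anxiety = c("peur", "angoisse*", "inquiet*", "anxieux", "terreur",
              "effroi", "panique"),
  anger = c("colère", "rage", "furieux", "haine", "énervé", "indign*",
            "scandale"),
  negemo = c("triste*", "chagrin", "pleur*", "larme*", "deuil", "douleur",
             "perdu", "peur", "angoisse*", "inquiet*", "anxieux",
             "terreur", "effroi", "panique", "colère", "rage", "furieux",
             "haine", "énervé", "indign*", "scandale", "horrible",
             "terrible", "mal"),
  social = c("ami*", "famille", "ensemble", "frère*", "soeur*", "voisin*",
             "parler", "discut*", "rencontre*", "gens", "communauté",
             "partag*"),
  prosocial = c("solidar*", "entraide", "aider", "soutien*", "don*",
                "bénévol*", "généreux", "secour*", "accueil*", "ong"),
  values = c("liberté*", "égalité*", "fraternité*", "république",
             "citoyen*", "démocratie", "laïcité", "valeurs"),
  i = c("je", "j'ai", "moi", "mon", "ma", "mes", "me"),
  attack = c("attentat*", "attaque*", "terroris*", "fusillade",
             "explosion", "assaut", "otage*")
)

# one concrete surface form per entry, used by the generators to emit
# words that the matching lexicon is guaranteed to hit
.demo_emission <- list(
  posemo = c("heureux", "contente", "joie", "merci", "bonheur", "sourire",
             "espoir", "fiers", "formidable", "magnifique", "super",
             "courage"),
  sadness = c("tristesse", "chagrin", "pleure", "larmes", "deuil",
              "douleur", "perdu"),
  anxiety = c("peur", "angoisse", "inquiet", "anxieux", "terreur",
              "effroi", "panique"),
  anger = c("colère", "rage", "furieux", "haine", "énervé", "indigné",
            "scandale"),
  negemo = c("tristesse", "chagrin", "pleure", "larmes", "deuil",
             "douleur", "perdu", "peur", "angoisse", "inquiet", "anxieux",
             "terreur", "effroi", "panique", "colère", "rage", "furieux",
             "haine", "énervé", "indigné", "scandale", "horrible",
             "terrible", "mal"),
  social = c("amis", "famille", "ensemble", "frères", "soeurs", "voisins",
             "parler", "discuter", "rencontre", "gens", "communauté",
             "partage"),
  prosocial = c("solidarité", "entraide", "aider", "soutien", "dons",
                "bénévoles", "généreux", "secours", "accueillir", "ong"),
  values = c("liberté", "égalité", "fraternité", "république",
             "citoyens", "démocratie", "laïcité", "valeurs"),
  i = c("je", "j'ai", "moi", "mon", "ma", "mes", "me"),
  attack = c("attentats", "attaque", "terrorisme", "fusillade",
             "explosion", "assaut", "otages")
)

# neutral vocabulary carrying no category signal
.demo_filler <- c(
  "le", "la", "les", "un", "une", "des", "et", "ou", "est", "sont",
  "dans", "sur", "avec", "pour", "par", "ce", "cette", "il", "elle",
  "nous", "vous", "ils", "aujourd'hui", "demain", "matin", "soir",
  "ville", "rue", "maison", "travail", "temps", "jour", "semaine",
  "chose", "monde", "voir", "faire", "aller", "venir", "dire", "prendre",
  "train", "café", "musique", "film", "livre", "photo", "match", "pluie",
  "soleil", "weekend")

#' Synthetic demo lexicon pack
#'
#' A small set of word-category lexicons (positive/negative affect,
#' sadness, anxiety, anger, social processes, prosocial behavior, shared
#' values, first-person singular, event-reference terms) used in
#' examples, tests and the synthetic generators. The pack is synthetic:
#' it is not the (licensed) French LIWC dictionary and carries no
#' psycholinguistic validation.
#'
#' @param categories Which categories to return; default all.
#' @return Named list of [lexicon()] objects.
#' @examples
#' names(demo_lexicons())
#' @export
demo_lexicons <- function(categories = names(.demo_words)) {
  categories <- match.arg(categories, names(.demo_words),
                          several.ok = TRUE)
  out <- lapply(categories, function(nm)
    lexicon(nm, .demo_words[[nm]], source = "synthetic demo pack"))
  stats::setNames(out, categories)
}

#' Filler vocabulary of the demo pack
#'
#' Neutral words used by the generators for tokens that belong to no
#' demo category.
#' @return Character vector.
#' @export
demo_filler_words <- function() .demo_filler

# emission forms for a category (internal; generators only)
demo_emission_words <- function(category) {
  w <- .demo_emission[[category]]
  if (is.null(w)) stop("no demo emission list for category '",
                       category, "'")
  w
}
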