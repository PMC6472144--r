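{"user_id":"agent0016","timestamp":"2015-09-15T00:29:56+0200","text":"ville livre pour photo nous magnifique monde ville soir ce la et elle dans","is_retweet":false}
{"user_id":"agent0004","timestamp":"2015-09-15T00:54:11+0200","text":"musique temps aller musique la sont elle ce un et me","is_retweet":false}
{"user_id":"agent0015","timestamp":"2015-09-15T06:55:21+0200","text":"temps discuter semaine jour match aujourd'hui chose film douleur les photo sourire","is_retweet":false}
{"user_id":"agent0001","timestamp":"2015-09-15T09:01:45+0200","text":"rencontre livre sourire soleil elle pluie énervé me","is_retweet":false}
{"user_id":"agent0028","timestamp":"2015-09-15T09:03:36+0200","text":"pluie ce est jour sur pluie soir venir chagrin pluie jour soleil","is_retweet":false}
{"user_id":"agent0017","timestamp":"2015-09-15T09:20:29+0200","text":"venir fraternité sont weekend livre chose venir moi bonheur communauté sont cette","is_retweet":false}
{"user_id":"agent0010","timestamp":"2015-09-15T09:23:48+0200","text":"musique ensemble et match est prendre venir sont énervé pour","is_retweet":false}
{"user_id":"agent0024","timestamp":"2015-09-15T09:30:03+0200","text":"panique film musique mon maison est travail semaine elle j'ai une weekend prendre","is_retweet":false}
{"user_id":"agent0009","timestamp":"2015-09-15T09:31:07+0200","text":"aller voisins musique fiers le matin elle république dire aujourd'hui merci","is_retweet":false}
{"user_id":"agent0011","timestamp":"2015-09-15T12:15:05+0200","text":"demain horrible travail livre ou café bonheur me semaine ce elle des","is_retweet":false}
{"user_id":"agent0005","timestamp":"2015-09-15T12:17:57+0200","text":"terreur soleil temps avec elle train est il est angoisse cette amis aller ou café","is_retweet":false}
{"user_id":"agent0021","timestamp":"2015-09-15T12:18:10+0200","text":"film des ou prendre ils café faire la pour","is_retweet":false}
{"user_id":"agent0023","timestamp":"2015-09-15T12:20:33+0200","text":"livre bonheur courage soir des espoir ou il ville nous","is_retweet":false}
{"user_id":"agent0030","timestamp":"2015-09-15T15:51:28+0200","text":"demain il dire vous panique la merci matin sourire pluie fiers","is_retweet":false}
{"user_id":"agent0006","timestamp":"2015-09-15T15:58:07+0200","text":"demain musique ville les soleil travail soleil merci il pour me parler vous livre pluie","is_retweet":false}
{"user_id":"agent0013","timestamp":"2015-09-15T18:02:39+0200","text":"monde semaine voir cette avec bonheur furieux ce une weekend temps","is_retweet":false}
{"user_id":"agent0012","timestamp":"2015-09-15T18:11:40+0200","text":"monde venir par aller larmes soir weekend dire deuil ou","is_retweet":false}
{"user_id":"agent0002","timestamp":"2015-09-15T18:16:17+0200","text":"venir panique perdu un moi il amis partage film","is_retweet":false}
{"user_id":"agent0016","timestamp":"2015-09-15T18:19:23+0200","text":"soleil courage rencontre ma nous jour fiers la un","is_retweet":false}
{"user_id":"agent0007","timestamp":"2015-09-15T18:41:20+0200","text":"monde une je est ville voir est ong super généreux","is_retweet":false}
{"user_id":"agent0004","timestamp":"2015-09-15T21:04:26+0200","text":"je ce énervé nous musique matin ensemble match un ce","is_retweet":false}
{"user_id":"agent0029","timestamp":"2015-09-15T21:15:34+0200","text":"ma rue effroi ou train ou formidable me bénévoles sur musique le","is_retweet":false}
{"user_id":"agent0026","timestamp":"2015-09-15T21:53:14+0200","text":"bénévoles il ville matin me prendre ce dire chose aujourd'hui magnifique","is_retweet":false}
{"user_id":"agent0009","timestamp":"2015-09-16T00:02:34+0200","text":"moi est et musique rue des sont voisins moi","is_retweet":false}
{"user_id":"agent0017","timestamp":"2015-09-16T00:19:59+0200","text":"dans le un prendre match match venir aujourd'hui ou frères il dire sont","is_retweet":false}
{"user_id":"agent0019","timestamp":"2015-09-16T00:33:26+0200","text":"amis et frères ils elle photo la famille semaine travail dans","is_retweet":false}
{"user_id":"agent0015","timestamp":"2015-09-16T00:38:10+0200","text":"ville cette maison ils je dans parler soir ou sourire discuter famille demain","is_retweet":false}
{"user_id":"agent0001","timestamp":"2015-09-16T00:39:06+0200","text":"photo laïcité rue ensemble terrible faire matin avec haine fiers sur inquiet","is_retweet":false}
{"user_id":"agent0028","timestamp":"2015-09-16T00:43:09+0200","text":"venir perdu jour semaine vous livre film cette matin espoir monde ou les","is_retweet":false}
{"user_id":"agent0010","timestamp":"2015-09-16T03:00:18+0200","text":"train sur musique joie gens le un démocratie","is_retweet":false}
{"user_id":"agent0005","timestamp":"2015-09-16T03:03:53+0200","text":"avec monde et dons match train le pluie des matin dans ong","is_retweet":false}
{"user_id":"agent0011","timestamp":"2015-09-16T03:14:46+0200","text":"sur bonheur maison soir pour chagrin ville dire pour je pluie je soleil","is_retweet":false}
{"user_id":"agent0024","timestamp":"2015-09-16T03:34:31+0200","text":"nous sur il monde cette et le par une film","is_retweet":false}
{"user_id":"agent0020","timestamp":"2015-09-16T03:42:32+0200","text":"fiers voir inquiet voir demain sourire sur film ce sont avec la temps livre par moi","is_retweet":false}
{"user_id":"agent0030","timestamp":"2015-09-16T06:01:01+0200","text":"larmes famille ma nous pour il elle je furieux ils ensemble match maison j'ai","is_retweet":false}
{"user_id":"agent0023","timestamp":"2015-09-16T06:17:19+0200","text":"match ils le parler weekend venir avec larmes il venir la ma","is_retweet":false}
{"user_id":"agent0003","timestamp":"2015-09-16T06:20:55+0200","text":"sur soleil film sur une monde discuter une mon monde soir heureux matin soir","is_retweet":false}
{"user_id":"agent0025","timestamp":"2015-09-16T06:22:24+0200","text":"match ville soeurs ville soir moi","is_retweet":false}
{"user_id":"agent0014","timestamp":"2015-09-16T06:24:56+0200","text":"semaine panique rue matin contente est dans film citoyens demain","is_retweet":false}
{"user_id":"agent0022","timestamp":"2015-09-16T06:25:42+0200","text":"dire il monde me monde sourire demain est ensemble une peur vous ma contente les","is_retweet":false}
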