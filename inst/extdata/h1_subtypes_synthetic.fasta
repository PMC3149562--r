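>Q02539 H1.1 synthetic
MSAAKAGALQGTAKAIKLRKNNKLKANRKAAKVSASAGGLKSASADKKSAASSSANNAAQ
SAKKAKAAAKVRAKKKVDAKANAKAGLRARKSALTAKDADITASSASAKAAQKVSSAVLA
KVRSAKLAIGKKKKKSAKGKLRGAKSADSAATPNKGGAKKETAESSAKEGAKLTAKAAKE
RESSPAKAVEKKAGVDAAVTAKATARRKKNVAKAV
>P16403 H1.2 synthetic
MSATAADAVAAAEAGAEVQVRKAAKALQEETPAKASAAARSAEATAKRVDSAKVSAAVSA
QGAAQRGGLKAKGAAKKSAKKDEKVSANSAGTAKLTAVTAKVSASAAKDKLGSAKGVAAA
DKAAKKLNAKGAAKLAAGAGLQNKGTPKKSAKKTPLKLEAKEKQLATAKDLASPAKKALK
KLAVKVNSAKAKKVKKAARGEIAKAAAAAAANK
>P16402 H1.3 synthetic
MSATAEVEGKRAAKAKKKTPAKAADGKIKAAAGVVSSALVDSANKTAKKKVSANGSAASA
KKARGRALVVGDKKAAEKASAAAKGDSAKSAATAAATAETAASASAAKEKGKLSARLKRK
LAEKAKLAANKENEEGAKKEGKKAKATPNKSARNTPAKRQEDKKARKTAAKAVSPKKAKT
AKKGEAKKSPKKVAGAAKAKLKDASALKKAAAVAIKKVVAK
>P10412 H1.4 synthetic
MSATAKGVAEKKAKAAKTPAKALGAVSARKKARAASADVGSAGRATAKDASAAKSAKSAD
GGKKLLAKIVAKKKKAKKSAELKDRSAISAATANRTAATAASASAVANLAVASANKVEVK
KLVKAKNNKVKVGAVQKKVAGTAKATPIKVSAATPVKEKIGAAVKEKAKGRSPAKAAAGK
AGKRAESPSKAEANRKGAIKKATAADKDKAKGKVGVANA
>P16401 H1.5 synthetic
MSATAKKKTATPDKKVQSPKKKVATAAAKVAKAKGKKGTAGAKSAIATAKALASAKALAA
SADKNVVKKKKKGQAEGDKKSAIDVEAASALSANTAERTAATAASASAKVEKAADSAEAA
LAAKVKAEAAKKKAKGQTPNKVADAEKNKKIAANTPAKNGDAQDKKKAKARNSPKKELKK
LAAKAVRASAVLAVEGDEADRKRAGRAAKKNKEKAAAAKKDKAKKK
>P07305 H1.0 synthetic
MTAASTSAGKINAKKAVKSAGSTAVNRRSAKEDAKEAKVKRQKVSSAKSAKLKAESAKLA
AGNKKSAKIISAKVKVTTAANNVTAAKRASASAGQKGSAKAKESAALIGTADKKDSAATP
GKDSAVILGASAKKTAAKKQTPAKAVAGADIKTPKKKVRKETAKAAKGEASAANGKKGVA
KAKKSSAARGAAAQ
>P22492 H1.T synthetic
MSATAAARSATALANKKDKKKTAGVAKKAKVTAKESANLKKVSASANATAAKSASAKKRK
RSARKAAVEKKAAGDDAAAAQSAKAASAKKNEQKEGVKRTAATAKSASALRSAKNKADSA
AKAKEASASALTAAGAESAKSASPKKGKTAAQKGLKRKTTAKTAASAAGKGDALNKVSAQ
SPAKGAESASAAANKAAERKKKKTSAK
>Q81ZA3 H1oo synthetic
MGIEVSASSADSSSSASAKTSSASAASAKADQSAAKKKKGNASAAKLAKDKDALAAAKKA
KKVKVATSARKKTSAKKAKKKTAEALQGKLLADAAKRTAAAKDKGAVEEKSAKAEETASA
VRSAAGEAAAAKKKADRKLAKKKRAAAAAKDKNADNRNRAVSAEDKKKAKKAKGAVIKRA
RRKEQKAAAQIGAETAAKLAGGAKIDKKKTASAGQLVKKSASAAKERAKSSTAAESSAAA
KSASASSAGSAIAKQATAAKSASSAAAGGKLGGKAASPTKEGKKKGDAAKKKVKAAQKKA
DKAGLAIKAKEKVDNQDVLTANNILVKAKAKKALLDSSAKSSALKK
>Q92522 H1.X synthetic
MDSAAKQVKVKATTAAKKNNLLNGIADSAGASASAKAANSAKKADREDASARANKTAAAN
DGQKESSAADAKIVAVKVLRAAENARDTAAGGSAKIGEKKATAKAAGGKAAEKSAKGAKG
KRRAAKAAKGEEDSAALKKAAKKDAKADRALARESALKVKAKEKAAIEAAKSALAAALKK
AAEKKKEAVGAARKKKKIKAAALNAEAAKQAKK
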