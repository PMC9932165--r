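>MaSp1_NTD type=MaSp1 terminus=N
LLSEHKMELQMARKKCEPSNILTNIGIQQFELSIATSQNTNHVALIVIHGCAPGPPVPAR
HMWSIYFEVLLAAVRFSEDCEKSRQRVDLISIMNASFQTMRYVQSNNSYENKAMISLYIK
SSVLQPLADANNGEGLIDAGGS
>MaSp1_CTD type=MaSp1 terminus=C
TKTKYTQELNKEFRVLNGIFPRGAYSDQDHMKFILLAVAGVAIAEISTVPNNTQTEDWSS
DLAARCNLTGTFKKTPNIKFGDEAIRLAERQYSTLSIPCSQSVPKGDLQFWGAYDLPFCL
RSMLEDWLTDANGPW
>MaSp2_NTD type=MaSp2 terminus=N
LFLNSAGRDRDAFLIFQVNNTTSLLLNFKELLEEQWLPSVRGGRKGKVGRDGNVKQTDGF
IMFTNGFMNVVWSPADRDGGLEEVSPGYDFALFEGVISGSANTGAYFPAVVVMRM
>MaSp2_CTD type=MaSp2 terminus=C
LKANSFDLGIAIVGRQPVIPKGSIAQLTALKLISLDIGRCAANRQKHVLAWAEHSRRAGV
DSLCMQRLETVQGGVRQAVIAMALKKKIPGGFYFGDGSYLNCGSIDCNFATKLPWVLPRA
NDNPGARVFRDIPCNLEVVGYRLVLKGGCD
>MiSp_NTD type=MiSp terminus=N
DLIAYFGGRLAAAEDGAERKKVPGSVCGKLLELDGLLTACFHECKSGRDRDYCVEEKNKG
RSRMQTCIATFVQPGFHSGNTNCINLSLETARDSTKACLFCVYQPTIIDWLLLVLVVLIK
>MiSp_CTD type=MiSp terminus=C
IVRLSLYEDKQCLKSELLCMKLTVELAESPLDPGKCKAVSVCDKLYNGRTSLTLDHKLGC
SLQVISSDSADDGQAKGTADPAHIVLPRGSPFVEGSAGLPNSASGVGVPFARREANVMCE
AREKKKNEYVEQFV
>FlSp_NTD type=FlSp terminus=N
LTPIQSSPEDIVRFYSFKEERFLLDLTRIVQGCRIGIGSVGIGRQGNKTPDHRSLKGCGI
FLEPDIPGGIAEQAPLEQVRRGIDVKVFKFFIAKDDAYPEGPNGRFGKDVI
>FlSp_CTD type=FlSp terminus=C
QDVGNKSKRPKAQAEDILVKPCAKPELVLTKHAVSIWCNLGQAGHQLARTLTGDEFYMLD
PTKSHVNVIRLDGVGVLGFQLAITQCGAALEEIPGRPRNEVSDHEIAVDTAITAQQVIRC
FAN
>TuSp_NTD type=TuSp terminus=N
MIYFPYLWFSILFLHEQGNSPQQKDIHSDFTRALSVAQRAQEGLGACDRRVDLTPVIDNG
KRALKVQSVNNGLLSGMKGPYKYYSTELYQQEMLKSLSAVGFGQGPCRVSAYPMSQVTDD
GNYTFTREE
>TuSp_CTD type=TuSp terminus=C
VSAYMNWGQAPSEADPRLLDSANNISPRGRYAIPEFDEFAEFLVDGFLACESGDDAAQRW
TFLQPEILQSKPKRLTWSLSMYDFLLKKTVRNDNVWLLTTDAQFIKMAAGRVDGGPLDAP
VKNEDQIASGDNHTFR
>AgSp_NTD type=AgSp terminus=N
WDAFIDAVPKLLDKSLTVCAMSQGRLFAKELQAFTAITTALDFLPNWGDGEGRLLDSRNE
TFEGDQFLLVNIIKLAIKVKGIPIRNSGARIWACACATYFEL
>AgSp_CTD type=AgSp terminus=C
GSVGAVSLLEPPASFIKWMNTLGEWAKTIATHIVWYGPIAQQKSRKGSTVAGTNGIILGA
HDHVRFASVRSALAIHELFAELFQTVGKRLGDEYEWARKRREAGDLFSAGTWTEKPYGIF
LKGRSMQAFQAKVKPDH
>AcSp_NTD type=AcSp terminus=N
QGPGETIDIILPDYELGLKNMGVLTYIVAGAVTGTCVLARHVRDSINGFLTHINLSVCFE
FLTGAYVLSEYFLSEDDLCEDLAGGFLNDLLIAQVKQPVVCAAILELQGSGANYAAAFTD
KTRNEKARALWGPERAVKSRKS
>AcSp_CTD type=AcSp terminus=C
PVMYAADKVPSAGQLVGATICNVRQGRSFMQEFVASSIVKLRENLQFSGSMKQGGTKVKT
TREQQCKYPMYTDVDAVQCVAVTAIKNDSAEAWDRKQVDCPNGREQLVQEDYHRQN
>PySp_NTD type=PySp terminus=N
LTAAAKTKFVVSEWLEELVSFPSVSGGIGKNYLLALTPICAVSRPKQLNSVKGNEGWTAC
KNYENSYNNFNQERTLASFEVGKDTAVNVNVAICLEEDFWSLYIDPKCVVCQNALGWELV
YGYEPVPKGKVQYVFMET
>PySp_CTD type=PySp terminus=C
KPITIQITNHEGLETPKMSEGDDKTATEGKRAFKIGYREGLEGNKADAFRTARADFKTDP
GYVLISNVSYAIYLDSIRTAYALEALGSMCTELALPCKVTKLTGINGQVILKTEGSDQSL
ASRGMYINLLQDLMRQLP
>other_NTD type=other terminus=N
GQKLNLLNSFPRVGDRVEQHGAASSGTHVILGAGTDRQGLHCFFIARMTPVTSIFPDRPH
LTIPIVSIDYAYSNIPVLVHEIKEKHKNLTVKLLFSYGGHYNGGRHEQKVRHGVRSVGSS
FTGWDYDIPPKLGTVHHNTITHEQYSE
>other_CTD type=other terminus=C
EVALKGVVATWQVKIPVTNPMGRSGSTDQGNEDSEMAIDIFAFGIMHSNQVDEEGALDTA
KAKNLRRAVLFYVRLNFIDATQSAFLLGVRANDVIITVQSNFAPLGECGKLKLSDTKTMI
NLEEDI
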