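taxon	length_bp
Astragalus acutirostris	123082
Astragalus agnicidus	123777
Astragalus americanus	122398
Astragalus ampullarioides	122944
Astragalus ampullarius	122592
Astragalus arrectus	122721
Astragalus bicristatus	122963
Astragalus bolanderi	122022
Astragalus calycosus	122244
Astragalus clevelandii	122656
Astragalus flexuosus	123578
Astragalus gypsodes	122194
Astragalus lentiginosus var. diphysus	123718
Astragalus lentiginosus var. mokiacensis	124016
Astragalus malacus	122967
Astragalus mollissimus	122511
Astragalus neglectus	122253
Astragalus nuttallianus	122840
Astragalus obscurus	121590
Astragalus pattersonii	122969
Astragalus pectinatus	123069
Astragalus serenoi	123386
Astragalus tephrodes	122693
Astragalus toanus	122573
Astragalus wootonii	122915
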