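trial_id,condition,true_target,f1,f2,f3,f4,f5,f6,f7,f8,f9,f10,f11,f12,f13,f14,f15,f16,f17,f18,f19,f20,f21,f22,f23,f24,f25
1,offset25,1,72.9835456501334,-23.6101245389319,91.3317711442738,-2.45606529328236,9.89938290853291,12.1467875040659,46.823135669984,-16.8015113306185,-14.6108538298819,31.5867562075524,-27.2768773560702,25.0022009422873,10.5145902829727,24.7283288177936,27.9714320537471,30.3009562501849,33.8414096177559,-23.1901559384182,20.3769187065432,1.95238009623802,-0.522604677835105,-16.9473549795223,23.1101142110842,41.463768995588,-48.9620040225198
2,offset25,2,-44.7644359988631,-34.757606838608,-40.066419606217,-54.7817657961781,-2.05232408092276,-18.5169302297037,-58.373317522032,-3.58010856858646,-76.0724899825838,-20.8293664701048,-76.4652509502879,14.3011375182988,13.9685108178871,-53.0098762283081,6.34479537925906,-45.4438139622431,-70.2900862919594,-65.2799447969487,26.6875598243234,18.7582811427551,9.9324117994197,-18.3493350504088,12.2670625018399,-68.493459470111,-15.4206654649355
3,offset25,1,37.7094943968069,20.333753226222,15.9955716030875,-59.4972677481321,36.2673842821381,45.3638304577927,6.00099148991502,17.4001053988718,27.7993893634406,24.1217607196409,29.3645835168952,75.3949510041666,8.16525054211063,6.32776845173472,16.9577651368807,37.9082356420585,-8.5709655533127,0.296251183395754,17.4039426467764,15.4882699711011,69.0468582608446,70.4197064861633,53.4618263094062,73.3551409734937,0.934110556480583
4,offset25,2,-2.84980882636359,-2.7417360675474,-86.7107079818173,-23.7357087587711,-52.4343629308131,23.9907889552437,-4.66512258114111,-31.3964847216173,-2.13784811227835,-21.2174545220289,-59.8823697209413,-63.3989818942038,-40.1609161410255,20.0686335954606,4.28166739612147,-14.687098109817,13.0021198787965,-61.8919523727017,-69.9260771432279,8.17831985563186,18.7102291083534,-61.1855803037663,-31.6785765936499,17.1560627953438,-9.3885631463347
5,offset25,1,39.149391309935,15.0511477504375,41.1034074190945,32.2099510070089,80.1504631927192,-0.455222081606276,51.8862558242107,57.6671214999906,67.0337881459473,8.00976674536663,24.9362084993352,20.8938153912438,49.3901901793236,18.8565945415255,-36.0769551467843,15.2259219330099,39.13212166505,2.39896969001281,38.4983761655191,-17.0553850538128,-23.3222967333866,-0.845426397457238,-69.4975432997296,53.8425887288658,-3.43346533267091
6,offset25,2,-28.7143580632019,-117.975939731667,-47.3998206586042,-37.6370054492033,-2.49852429989393,20.588992121545,-8.76813440109415,3.76205886778872,11.5662880508704,-42.6475995740766,-39.9890608499035,17.0524440321895,-61.9728944609818,-62.5123834452737,34.1310622459681,-71.7682829212604,-4.47293621482457,-31.4882288686776,-37.3029505735182,-41.3140633731426,46.7486242772738,-23.3702621192198,-22.8661676419609,-83.1920290764958,52.4219418117297
7,offset25,1,77.9032699103629,-60.4163425001432,40.9407543134427,51.5357132494831,28.1416226309862,36.7546841913226,-6.00217040933878,73.7240731576995,-10.1123026393947,-33.1384677970184,3.52149377426766,8.55946468017947,23.5755533697075,30.7122408863584,55.2672292481502,49.5262086454012,88.5329956153883,-17.0427717758995,6.73713673253058,15.5727011696387,60.590549042984,-10.6158641939137,45.0813094119252,5.07427797380817,20.67029099479
8,offset25,2,-28.3130663444584,21.2039671005567,-0.33069319699133,-50.4346689476801,-15.3207238447988,11.3477134544167,-63.4923314526749,-41.6660873069136,39.6968665585461,-38.3816804405836,-95.8637245896688,-26.8364319728649,-79.3040687821656,-37.6958445469782,-30.2771596110012,-5.60311822040883,-20.4912499989166,46.2940258444103,-62.384592024051,-38.6837892845801,-25.935111244839,-38.4149385960197,-23.3968747096215,-2.75701639486658,-41.7067427110518
9,offset25,1,95.6448299856965,14.2676492072534,61.2286232689473,-22.8898365546753,48.7751085619345,57.2254998901726,77.9447453431725,47.7621996254207,1.6629306934764,7.05724097427699,-17.8661782625995,21.9862445617019,65.8509342232489,45.6504741795569,-25.7152495548709,-4.27073074804953,-45.0325233206029,28.7721160709941,39.9928066143342,72.20474541971,49.6262722579391,55.5464394084989,30.5094389061556,26.530270265225,19.1808477979687
10,offset25,2,-27.1949934668347,-87.3457951893,-46.3124231392524,-9.8513690938949,-21.8558489697321,0.230735700340187,-15.9727496863789,23.68886597365,-21.3070165640376,69.5661850120679,-18.7169245608722,-56.0687656267251,-34.5775995480928,25.1347674705846,-2.49469549853064,-80.8105856702185,-13.317798089825,-27.9437835176953,-31.0906382049448,-25.7967645454444,-58.9984830203152,8.9340754889541,-9.89521194959302,-12.8195693718543,5.18971842692508
11,offset25,1,70.670437897822,18.9828925484133,42.673429315429,-3.39876116653351,-79.7581529103527,-11.5091628498749,28.0954080205855,-13.8776107806765,10.22104413459,-22.6740680916402,44.8667208048237,9.43605982903417,8.62541363647113,-9.74423788883225,41.9117852335169,32.1735503205672,65.9963794575578,42.3466874561608,43.048370502681,33.5479047886208,-13.36546845456,38.4346332759483,11.1207592382426,111.085774210465,28.4069169820987
12,offset25,2,55.0325887445387,17.513614471041,-85.095303767567,25.5435441602438,-15.0290966264269,-28.1565235313747,-29.2313788138681,-55.1277405407245,-29.282256018424,-20.1960323504488,-42.2507073743716,-26.0305707680883,-68.3388314795175,-9.08723958469011,-25.2224469247486,-37.0780792290511,47.0838734804757,-23.6904684858712,-33.2027847057073,-57.9830097752373,-23.2832342171841,-89.8044482073613,20.8492379013042,-53.6433113539884,-81.8965858723951
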