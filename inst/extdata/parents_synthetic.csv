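id,g_leak_axon,g_Kd_axon,g_A_axon,g_Na_axon,g_leak,g_MI,g_Kd,g_A,g_KCa,p_Ca,g_h,g_synAB,g_synPD,g_synPY
1,0.01206752889149921,5.1315657017570384,0.73429695353649937,28.208152323712461,0.030149780531483192,0.031444508288395304,1.2024959968809681,1.2477612378518077,5.2808551178385983,1.5706028849297834e-05,0.40351929398827674,0.4781940283177083,0.50041040823964955,0.7824079998079343
2,0.0060506985542271565,3.5003954375880113,0.48686923274252769,29.382541190668839,0.05010096014979179,0.04096529976987804,1.5066277595466535,1.0966616568489229,4.9716861779425976,1.4682377008216525e-05,0.48089043435517353,0.43985026135953453,0.34600571290887205,0.81296212723066175
3,0.008898319055198509,2.6445145364246514,0.53357485080157241,36.412286942459069,0.037038461978876357,0.030364610954810925,1.1411682594569745,1.1862547717015697,3.9495704473227824,1.7434930496599899e-05,0.52097136038374714,0.46030726268958683,0.42679671047236578,0.46977217248501141
4,0.0068888528935699411,3.713796819706384,0.45258716905690299,28.351484533446484,0.036549431452623148,0.029835889414001723,1.0054633384370972,0.67502181800074879,4.5184550114491531,1.2822435543763883e-05,0.50915901877971059,0.36380199592141199,0.49809238292564717,0.54225785628857637
5,0.0095691834539395424,3.7306616631701015,0.51082968362335657,26.099564233876379,0.04759355600947654,0.031072259205532613,1.5444248181553952,1.2864994315615856,4.2913930088456116,1.5773517472507328e-05,0.33944430584536484,0.37362639575339435,0.43210998766174535,0.6555034903784418
6,0.010404835909552861,5.2149781420386585,0.4947806242592413,37.664733306091513,0.049562607388991681,0.041272921969960158,1.2182500069722151,0.96042743594163849,4.0993822962327666,1.694411568257855e-05,0.2650319331543225,0.26119517266534031,0.39272540400207356,0.69952401124213792
7,0.0062979322549093679,4.2878350612320189,0.80729292594557656,32.583525285854819,0.047145041637902105,0.043849354962051737,0.89047769982556202,0.72587330313529219,3.9413780704445691,1.7451751171684438e-05,0.300430155790886,0.28364708573232539,0.27347797642764171,0.44937570772034546
8,0.01138960147802779,2.5645293619007337,0.74967640687510628,21.599401630479971,0.044555545424253121,0.05286678523098963,0.84413710067370762,0.9569334016410751,4.566265753580188,9.8621744514336266e-06,0.4103039096571105,0.48298234920547367,0.5262406882563444,0.68577448279267106
9,0.006841556638564162,5.132583160322854,0.68106868997865688,41.964832839109576,0.043495668281670521,0.041733815083148371,1.157497718026097,1.2656773167815474,4.7070926264826038,1.4798155849041989e-05,0.36367889290236516,0.40256881227278618,0.52330472113833104,0.56481588173957675
10,0.0085736772125938106,3.2824797002159154,0.4596558445177833,39.164816642683711,0.02833942052112124,0.040131533981836692,0.99145170025450413,0.98637347822602794,5.5497576740050558,1.3743884614629594e-05,0.4540152729758638,0.41012586303086918,0.34583434182353973,0.56312259704582057
11,0.0092867443619055277,2.5901904281421397,0.65303024815897626,31.911543906787205,0.027683609260244435,0.049409688515292954,0.78516863256782854,1.0584841577658202,3.8489394593705395,1.5958237882890719e-05,0.40042524521413625,0.49519592035575205,0.46929755472092416,0.53551590749665801
12,0.011841945411004355,2.756000095951876,0.80592844525599561,22.981733211380313,0.036228307684661537,0.054444765558028893,1.0918170877721198,1.0405287175876796,4.9624454830895806,1.4480024213567576e-05,0.38550424478788936,0.28944599515912284,0.32744712667836584,0.7171078409884315
13,0.0083400137583564404,3.445333554670404,0.71702187758607516,41.930189955159129,0.034127565317374001,0.034870826092214854,1.242468313414556,1.0755592086357386,5.97673502902731,1.1121009215654679e-05,0.46097023199982656,0.40521811441422018,0.47361938668189474,0.75887221327852861
14,0.0095283298722993494,2.5338784041907285,0.88256077764750995,20.977083309936575,0.035836608899751862,0.02947069028248487,1.5980293303120723,0.79937607333497107,3.6708834709968841,1.5619496140772645e-05,0.38554899654950864,0.29500435849611534,0.32192422779703078,0.65213741527474756
15,0.0091770738677229898,3.2141410377305619,0.54813247900797712,29.659126767726473,0.025081762699574791,0.028593109712719163,1.3491831197916115,0.90348458024333,3.267202434990935,1.3680194679116928e-05,0.37722106774357378,0.3694927790451209,0.27164475190356441,0.73766241992562875
16,0.010378898792909879,3.3032601806718995,0.52662122310392467,35.733438503416963,0.048666498869095701,0.054354568173437444,1.2977936097278939,0.74795767309989369,5.823418352248221,1.6066640732300775e-05,0.36936926570936901,0.37804922847143563,0.41367657418051806,0.47707782936609061
17,0.0078687756585333942,2.5671607919465989,0.52907087114290774,27.386678277486876,0.044418870165283418,0.051099149503262602,0.940111464667994,0.76406571218777319,5.7742172323650358,1.6246992459504427e-05,0.38340834062089901,0.4642702656585963,0.41090522079696629,0.69603262168245916
18,0.006640489862567189,2.7172391546500321,0.50882042967987517,37.343191576321082,0.037497020697648216,0.029423245635112401,1.3568257205353857,1.0825815276005151,4.7940129517921699,1.1424977224246533e-05,0.43081334168411672,0.36894544008066688,0.39602576760986996,0.71840174271932011
19,0.011341694673427639,4.5306101376699655,0.66887893855834957,39.680812154593561,0.038913784597021578,0.028125963598911768,1.3836122067313648,0.69363338870518054,3.4089594483028103,1.5361819372574196e-05,0.36922942990719443,0.35058261244978844,0.36834312894567356,0.54430770170191667
20,0.012196415837776246,5.0374565408937055,0.55138618164937947,35.370546673992564,0.044324862695227327,0.05535444455712045,0.93568870123959424,1.2138618579744715,4.3386019232701534,1.7303578750388292e-05,0.35404417691020201,0.47719672751493547,0.36608479505682345,0.80384893671954727
21,0.0065309844108828417,2.9917709074082937,0.67405674676487648,23.830925647916946,0.045415205161704358,0.047236447932544695,1.28727583960102,0.97856719597296327,5.273290988262664,1.7213546413582396e-05,0.44334514783371226,0.47346528988175079,0.38884058997183968,0.80510682527193111
22,0.0071303622552656076,5.2202374943131851,0.65868199317124554,31.993958275336805,0.043495903145176498,0.040445118294640564,1.3026356478916257,1.2098434285567543,4.6441646791381661,1.5481513752084148e-05,0.45202426882615937,0.35370983179544335,0.32113188597328302,0.57495737158756621
23,0.010791542126321723,2.5520155667170954,0.56920895463055843,29.537443241175328,0.045302039431697409,0.030620474680379269,1.0220654983668751,1.0137603293200927,4.0269831023911546,1.3838133074051267e-05,0.36863916684301645,0.27380701269685281,0.2901597005258319,0.5036937376112407
24,0.011109070359198269,3.4420679431404602,0.44902471154120371,23.433420391630676,0.040625011791589394,0.050901762700607658,1.4909416929550721,0.90916374646770537,5.8819483411097009,8.9721853654796862e-06,0.31706759258796258,0.31463715940061437,0.53455275283968451,0.53537684508054417
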