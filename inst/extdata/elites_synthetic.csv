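id,g_leak_axon,g_Kd_axon,g_A_axon,g_Na_axon,g_leak,g_MI,g_Kd,g_A,g_KCa,p_Ca,g_h,g_synAB,g_synPD,g_synPY
1,0.0092399785139438279,4.1872269353033946,0.69425524711950082,29.157986941925028,0.034715646534666446,0.042309985199031556,1.1131439890033346,0.99444818962486514,4.6162276312534676,1.3155331629454734e-05,0.39418914472338146,0.36134875840881908,0.43211914915621191,0.59479892430241343
2,0.0094284450272702387,4.0736588131355704,0.69504603485736494,32.286493287633611,0.03584659581411892,0.043614811344079331,1.2694124321693128,1.0883520383412644,4.7469752786094439,1.3688533757533943e-05,0.43575845812286806,0.3930609407758871,0.42914127224432352,0.61463662060180468
3,0.0094106607223562629,3.6829645813845984,0.6681884919906832,32.57889415049771,0.038909122791990151,0.043342375259256022,1.2030470111402638,0.98213123281974846,4.8839331723538901,1.2147392697468672e-05,0.40730038587661638,0.38233069077177839,0.42240549164131497,0.61860954030023707
4,0.0089181268570702101,3.8364712826634069,0.67240475189267568,29.842450762817666,0.037234685316911292,0.04363925412244786,1.0997514566911992,1.0916365251692564,4.4674456711713466,1.3154228188191036e-05,0.43612699374538871,0.39157576621963675,0.41421994730559225,0.64935025361685184
5,0.0092571930248640678,4.1442565923776042,0.63499332315557666,29.112662016661886,0.034641935755969376,0.042284663417452149,1.1071475343595953,1.0251466629092405,4.2509458813998462,1.273943500408166e-05,0.38138682904437304,0.37889878917676695,0.41375637672521332,0.58739272679289056
6,0.0095944335272069147,3.9171446210708867,0.68420515248408831,33.571349845082715,0.039013124471446163,0.044107568288000179,1.1065077099320895,1.0708947825054445,4.7673717941111118,1.2252433373141541e-05,0.3746736352120435,0.35363688987780717,0.44566405038470103,0.59946491620571729
7,0.0084582554357541355,4.0640802842812596,0.67901255693164486,32.850385925384096,0.039760909811825722,0.041855142545583424,1.1880193149396434,1.0608843482495802,4.4543286965865008,1.2971136631054644e-05,0.40962650086726038,0.39410506398731859,0.38685133194663002,0.64705459002461296
8,0.0083663175366995267,3.8452073994041176,0.65377901590031162,33.506841715970396,0.035365436461545864,0.043083074089591528,1.2531737839291788,0.94553732816245806,4.6531267987816314,1.3341464865580112e-05,0.40930651534436413,0.34995282150092122,0.41700088504098398,0.66752846154158996
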