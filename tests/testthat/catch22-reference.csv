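"series_id","DN_HistogramMode_5","DN_HistogramMode_10","CO_f1ecac","CO_FirstMin_ac","CO_HistogramAMI_even_2_5","CO_trev_1_num","MD_hrv_classic_pnn40","SB_BinaryStats_mean_longstretch1","SB_TransitionMatrix_3ac_sumdiagcov","PD_PeriodicityWang_th0_01","CO_Embed2_Dist_tau_d_expfit_meandiff","IN_AutoMutualInfoStats_40_gaussian_fmmi","FC_LocalSimple_mean1_tauresrat","DN_OutlierInclude_p_001_mdrmd","DN_OutlierInclude_n_001_mdrmd","SP_Summaries_welch_rect_area_5_1","SB_BinaryStats_diff_longstretch0","SB_MotifThree_quantile_hh","SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1","SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1","SP_Summaries_welch_rect_centroid","FC_LocalSimple_mean3_stderr"
1,0.548686942588711,0.236794167802405,0.647354166602966,2,0.0294529154782415,0.0131227734766814,0.963927855711423,10,0.00099460761385569,4,0.0899441462945275,4,0.5,-0.0978043912175649,0.125748502994012,0.161183417099534,4,2.19346446490451,0.130434782608696,0.883720930232558,1.49716524897639,1.16905877364701
2,0.128848951118196,-0.786887278555646,4.61238311025895,12,0.189114888237434,-0.0424653381878562,0.947895791583166,28,0.0147737765466297,19,0.208702011279717,12,0.0384615384615385,-0.0578842315369261,0.512974051896208,0.78073309585041,7,1.90180429619222,0.304347826086957,0.13953488372093,0.269980618667873,0.734191329541011
3,1.11107636649456,0.887493346859362,18.2816755726115,2,0.485113433224162,0.0160680440054596,0.953907815631262,46,0.00646352723915051,96,0.328565802277741,2,0.0384615384615385,-0.093812375249501,0.101796407185629,0.852731373398634,5,1.73572948011332,0.760869565217391,0.674418604651163,0.0736310778185108,0.471664053051871
4,0.0628016333442141,0.312594995833208,72.8760021924387,3,0.236348046091957,0.0120785725696888,0.977955911823647,59,0,7,0.142425583982896,3,0.00549450549450549,0.746506986027944,-0.732534930139721,0.508918409459462,4,1.97649362305507,0.630434782608696,0.767441860465116,0.0490873852123405,0.682789703190536
5,0.65685644310348,0.484472259301517,0.625995954102682,4,0.0127848338702951,-0.112792962639736,0.977955911823647,9,1.20481443849623e-05,5,0.11216030787415,2,1,-0.0538922155688623,0.062874251497006,0.204836050986502,4,2.19711221684232,0.173913043478261,0.883720930232558,1.5707963267949,1.14634820943074
6,0.132550347134789,-0.195131248873696,0.456628770088034,3,0.0186190771528468,-0.839210405528496,0.983967935871743,6,0.00452207019248919,6,0.0468863893663456,4,1,-0.0249500998003992,-0.2375249500998,0.064969542127052,4,2.15561552945544,0.130434782608696,0.790697674418605,2.25801971976766,1.17949226504822
7,-0.24741220497875,0.0357655240404582,0.868847097895414,9,0.0689498541982585,-0.11489777548708,0.963927855711423,10,0.0012563644779475,23,0.138196868280082,6,0.142857142857143,0.00598802395209574,0.0618762475049901,0.445245603694174,4,2.16493627607104,0.369565217391304,0.186046511627907,0.859029241215959,1.00045908885407
8,-0.333838629565195,-0.522404154927247,65.7909198003019,173,1.09473785453564,7.73319272614451e-05,0.667334669338677,119,0.0625,0,1.79506982249942,40,0.00970873786407767,0.812375249500998,0.0738522954091816,0.561851691370476,7,1.38037410127004,0.130434782608696,0.883720930232558,0.0245436926061703,0.11070086119774
9,-0.564449512297072,-0.080182726436371,0.631342051103207,4,0.00995550051313868,0.0214606659658963,0.985971943887776,11,5.08699429587298e-05,5,0.0484259318829335,4,1,-0.0658682634730539,0.0978043912175648,0.202687564719856,5,2.19675355137853,0.152173913043478,0.13953488372093,1.61988371200724,1.13336372045585
10,-0.0242358265968683,-0.314948899553481,5.5408951000181,17,0.220632952975437,-0.0272775788304777,0.971943887775551,31,0.00756143667296786,25,0.234704520352121,17,0.0476190476190476,-0.170658682634731,0.131736526946108,0.828324367757594,5,2.00234246364638,0.304347826086957,0.209302325581395,0.196349540849362,0.725407159721545
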