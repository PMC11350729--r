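# type: trace
# t_dead: 0.002
# observable: fluorescence
# sigma: 0.0004284249739317342
# mix: E 0.1 uM + S 10 uM
# conc0: E=0.1;S=10
time,signal
0.0025249752961773492,0.99398397718174325
0.0050499505923546984,0.98931373903042030
0.0075749258885320480,0.98427052119934888
0.0100999011847093968,0.98034615167633032
0.0126248764808867455,0.97774075711255315
0.0151498517770640960,0.97337970890138459
0.0176748270732414448,0.97109268079729449
0.0201998023694187935,0.96771663079771253
0.0227247776655961423,0.96451342231377102
0.0252497529617734910,0.96133528800243184
0.0277747282579508398,0.95878150562768338
0.0302997035541281920,0.95648835505505514
0.0328246788503055373,0.95360273621799352
0.0353496541464828895,0.95189299255489668
0.0378746294426602348,0.94936108050898038
0.0403996047388375870,0.94781529678926946
0.0429245800350149392,0.94577055478068273
0.0454495553311922845,0.94439736485622205
0.0479745306273696367,0.94200448711303408
0.0504995059235469820,0.94030421725506430
0.0530244812197243343,0.93870130558699982
0.0555494565159016795,0.93747311132972977
0.0580744318120790318,0.93585030808301461
0.0605994071082563840,0.93482123187765587
0.0631243824044337293,0.93339859650219736
0.0656493577006110746,0.93213092222690563
0.0681743329967884337,0.93086853582787954
0.0706993082929657790,0.92949941447120388
0.0732242835891431243,0.92866599867788147
0.0757492588853204696,0.92732458254414829
0.0782742341814978287,0.92630763405465755
0.0807992094776751740,0.92546064570789310
0.0833241847738525193,0.92527992744846776
0.0858491600700298785,0.92348255906669297
0.0883741353662072238,0.92299542393990586
0.0908991106623845690,0.92282404579077348
0.0934240859585619143,0.92182162142703927
0.0959490612547392735,0.92188329252067647
0.0984740365509166188,0.92031218842980300
0.1009990118470939641,0.91980966749550230
0.1035239871432713232,0.91867208326996463
0.1060489624394486685,0.91882504491293093
0.1085739377356260138,0.91866862317553089
0.1110989130318033591,0.91740877139073618
0.1136238883279807182,0.91768467541811860
0.1161488636241580635,0.91670008421477378
0.1186738389203354088,0.91547682676972042
0.1211988142165127680,0.91637817966064017
0.1237237895126901133,0.91591882189965157
0.1262487648088674586,0.91532959635096345
0.1287737401050448038,0.91521871449465508
0.1312987154012221491,0.91444400535573189
0.1338236906973994944,0.91387057327250520
0.1363486659935768675,0.91412970846248920
0.1388736412897542127,0.91369308730466992
0.1413986165859315580,0.91358081430157712
0.1439235918821089033,0.91301817049095113
0.1464485671782862486,0.91302304222884423
0.1489735424744635939,0.91323446800957786
0.1514985177706409392,0.91239638681801960
0.1540234930668183122,0.91179149823377359
0.1565484683629956575,0.91295274936442761
0.1590734436591730028,0.91170356156730803
0.1615984189553503481,0.91073459624443709
0.1641233942515276933,0.91162457789442752
0.1666483695477050386,0.91195159101005607
0.1691733448438823839,0.91072762341795688
0.1716983201400597570,0.91045405394324508
0.1742232954362371022,0.91050992401929809
0.1767482707324144475,0.91095622886478145
0.1792732460285917928,0.91069667386593056
0.1817982213247691381,0.91032525131396813
0.1843231966209464834,0.90993300387094556
0.1868481719171238287,0.91024529510671282
0.1893731472133012017,0.91052015236049111
0.1918981225094785470,0.91000589128835330
0.1944230978056558923,0.90954695044926692
0.1969480731018332376,0.90994403847541971
0.1994730483980105828,0.90920505535801255
0.2019980236941879281,0.90975116556624003
0.2045229989903652734,0.90947214268027554
0.2070479742865426465,0.90955969233091682
0.2095729495827199917,0.90909334494736405
0.2120979248788973370,0.90889580676420634
0.2146229001750746823,0.91018869906489575
0.2171478754712520276,0.90889962621666698
0.2196728507674293729,0.90854333079618110
0.2221978260636067182,0.90926051005225828
0.2247228013597840912,0.90862483341591982
0.2272477766559614365,0.90829468114481005
0.2297727519521387818,0.90940695405869532
0.2322977272483161271,0.90840577042705528
0.2348227025444934724,0.90920462864201013
0.2373476778406708176,0.90852858677512005
0.2398726531368481629,0.90894176527282278
0.2423976284330255360,0.90853345737169566
0.2449226037292028813,0.90921723501105112
0.2474475790253802265,0.90812658069339847
0.2499725543215575718,0.90918824860974423
0.2524975296177349171,0.90829420645033854
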