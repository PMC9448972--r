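year,summer_mean_temp,winter_min_temp,snow_days,spring_temp
1990,13.5841545184127,-13.8930017470212,82,10.6100576709052
1991,15.3596832334279,-14.3507104937962,50,11.2748658278786
1992,13.8577117244099,-16.0332283293536,52,9.65816313295679
1993,15.1680024881554,-5.57221041392233,50,10.3333301638899
1994,14.2441355655282,-9.78456321648147,2,11.2652994189352
1995,17.6445467457496,-15.6226333555758,55,10.0823598657077
1996,15.2673364349478,-10.3311336994304,36,10.8398127891736
1997,15.1002147077694,-16.7922277331643,18,11.5060070057071
1998,14.4121584342943,-12.6955123017429,60,10.9375258064869
1999,16.2147529416105,-10.9703797137787,70,12.6530145618744
2000,13.9473948729191,-12.9160983068152,42,10.0453839192105
2001,14.8381337241489,-8.19395851140545,86,9.61136883935062
2002,12.4112401066994,-14.0309364881651,0,10.3012169106706
2003,13.9525727344246,-15.1266305940574,92,10.7334989270223
2004,12.7997572178343,-15.645378600936,52,13.8780502586313
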