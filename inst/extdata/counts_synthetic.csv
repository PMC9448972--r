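year,eggs_laid,eggs_hatched,larvae_l5,first_egg_date,first_l5_date,dev_time_days
1990,374,223,1,1990-06-20,1990-08-07,48
1991,93,58,8,1991-06-17,1991-08-07,51
1992,70,42,3,1992-06-15,1992-08-01,47
1993,156,109,30,1993-06-09,1993-07-10,31
1994,972,581,24,1994-06-14,1994-08-03,50
1995,491,309,32,1995-06-16,1995-07-15,29
1996,902,568,31,1996-06-07,1996-07-14,37
1997,583,366,35,1997-06-14,1997-07-27,43
1998,582,371,28,1998-06-03,1998-07-22,49
1999,884,558,61,1999-06-10,1999-07-09,29
2000,717,451,66,2000-06-19,2000-07-26,37
2001,557,344,5,2001-06-22,2001-08-11,50
2002,78,46,6,2002-06-15,2002-08-03,49
2003,321,210,24,2003-06-04,2003-07-15,41
2004,746,448,8,2004-06-07,2004-07-27,50
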