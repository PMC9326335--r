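"wavelength_nm","eps_HbO2","eps_Hb"
440,271746.2,414095.4
442,245520.7,398704.4
444,220103.3,381251.6
446,195785.4,362063.4
448,172802.9,341485.8
450,151335.8,319874.3
452,131508.8,297583.6
454,113395.3,274958.3
456,97021.4,252324.5
458,82371.9,229982.3
460,69396.7,208200.5
462,58017.4,187212.2
464,48134.1,167211.5
466,39631.8,148353.3
468,32386.1,130752.9
470,26268.4,114487.6
472,21150.5,99599.4
474,16907.8,86098.4
476,13422.1,73966.4
478,10584.1,63161.8
480,8293.8,53623.7
482,6461.8,45276.5
484,5009.3,38034.3
486,3867.8,31804.3
488,2978.6,26491.2
490,2292,21999.5
492,1766.5,18236.7
494,1367.9,15114.8
496,1068.4,12552.6
498,845.6,10476.5
500,681.8,8821.8
502,563.6,7532.8
504,481.4,6563.5
506,429.9,5877.5
508,409.4,5447.8
510,427.6,5256.5
512,503.4,5293.9
514,672.6,5558
516,993,6052.7
518,1550,6786.9
520,2457.7,7771.9
522,3852.8,9019.5
524,5876.8,10539.7
526,8645.7,12337.5
528,12208.5,14410.4
530,16503.6,16746.2
532,21326.2,19320.1
534,26321.1,22094
536,31012.6,25015.5
538,34873.4,28018.2
540,37419.9,31023.6
542,38311.7,33943.7
544,37426.2,36685.1
546,34886.9,39153.4
548,31037.3,41258.5
550,26367.7,42920.5
552,21423.1,44074.1
554,16717.6,44673.1
556,12683.5,44693.7
558,9661.6,44135.8
560,7923.5,43023.2
562,7696.2,41401.8
564,9151.3,39336.9
566,12336.2,36908.1
568,17056.7,34205.3
570,22770.1,31322.3
572,28572.4,28352.1
574,33343.2,25382
576,36037.7,22489.5
578,36017,19739.5
580,33268.6,17182.8
582,28401.6,14855.1
584,22419.6,12777.8
586,16381.2,10959.3
588,11103.2,9396.7
590,7012.6,8078.1
592,4166.2,6985
594,2374.4,6094.5
596,1349.3,5381.7
598,814.7,4821
600,560.3,4387.5
602,449.9,4058.4
604,406.5,3813.1
606,391.5,3633.9
608,387.3,3505.6
610,386.9,3416
612,387.8,3355.1
614,388.9,3315.1
616,390,3290.2
618,391.2,3275.7
620,392.2,3268.4
622,393.2,3265.9
624,394.1,3266.4
626,395,3268.8
628,395.8,3272.2
630,396.5,3276.1
632,397.2,3280.1
634,397.8,3283.9
636,398.3,3287.5
638,398.7,3290.8
640,399.1,3293.5
642,399.4,3295.9
644,399.7,3297.7
646,399.9,3299
648,400,3299.7
650,400,3300
652,400,3299.7
654,399.9,3298.9
656,399.7,3297.6
658,399.4,3295.8
660,399.1,3293.4
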