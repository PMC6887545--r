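wavelength,value
380,3.3782583e-4
381,3.9769158e-4
382,4.6798637e-4
383,5.5049378e-4
384,6.4729626e-4
385,7.6082418e-4
386,8.9391261e-4
387,0.0010498672
388,0.0012325403
389,0.0014464196
390,0.0016967301
391,0.0019895525
392,0.00233196
393,0.0027321758
394,0.003199756
395,0.0037457997
396,0.0043831921
397,0.0051268842
398,0.0059942151
399,0.0070052837
400,0.0081833757
401,0.009704795
402,0.011470116
403,0.013508141
404,0.015848514
405,0.018521045
406,0.021554865
407,0.024977377
408,0.028813034
409,0.03308192
410,0.037798184
411,0.043019943
412,0.048823953
413,0.055244296
414,0.062310404
415,0.070045392
416,0.078464241
417,0.087571858
418,0.097361072
419,0.10781064
420,0.11888331
421,0.13070433
422,0.14343129
423,0.15704813
424,0.1715168
425,0.18677375
426,0.20272651
427,0.21925074
428,0.23618799
429,0.25334435
430,0.27049034
431,0.28790585
432,0.30598963
433,0.32464845
434,0.34376635
435,0.36320334
436,0.38279459
437,0.40235032
438,0.42165632
439,0.44047548
440,0.45855019
441,0.47617063
442,0.49377148
443,0.51129668
444,0.52868798
445,0.54588513
446,0.56282623
447,0.57944799
448,0.59568608
449,0.61147547
450,0.62675084
451,0.64165915
452,0.65638995
453,0.67094337
454,0.68532167
455,0.69952928
456,0.71357269
457,0.72746044
458,0.74120309
459,0.75481313
460,0.76830497
461,0.78186143
462,0.79559894
463,0.8094289
464,0.82325619
465,0.83697911
466,0.85048942
467,0.8636725
468,0.8764077
469,0.88856878
470,0.9000246
471,0.91084136
472,0.92115801
473,0.9309495
474,0.94019108
475,0.94885836
476,0.95692742
477,0.9643749
478,0.97117811
479,0.97731512
480,0.98276489
481,0.98746992
482,0.99139633
483,0.99456086
484,0.99698218
485,0.99868077
486,0.99967881
487,1
488,0.99966948
489,0.99871366
490,0.99716012
491,0.9949717
492,0.9920891
493,0.98850869
494,0.98422868
495,0.97924915
496,0.97357213
497,0.96720165
498,0.96014374
499,0.95240652
500,0.94400014
501,0.93500518
502,0.92547134
503,0.91536656
504,0.90466237
505,0.89333414
506,0.88136126
507,0.86872731
508,0.8554203
509,0.84143274
510,0.82676182
511,0.811469
512,0.79565602
513,0.77938364
514,0.76271172
515,0.74569887
516,0.72840218
517,0.71087693
518,0.69317639
519,0.67535158
520,0.6574511
521,0.63948359
522,0.6214508
523,0.60338822
524,0.58532998
525,0.56730877
526,0.5493558
527,0.53150074
528,0.51377168
529,0.49619516
530,0.47879613
531,0.46158771
532,0.44458303
533,0.42780459
534,0.41127336
535,0.3950088
536,0.37902886
537,0.36335008
538,0.34798755
539,0.33295505
540,0.31826503
541,0.30393172
542,0.28996353
543,0.27636315
544,0.2631332
545,0.25027623
546,0.23779463
547,0.22569058
548,0.21396598
549,0.20262241
550,0.19166103
551,0.18108566
552,0.17090126
553,0.16110942
554,0.15171039
555,0.14270317
556,0.13408551
557,0.12585396
558,0.11800397
559,0.11052989
560,0.10342508
561,0.096679821
562,0.090284118
563,0.084229561
564,0.078506975
565,0.073106512
566,0.068017745
567,0.063229765
568,0.058731274
569,0.05451068
570,0.050556187
571,0.046856355
572,0.043398955
573,0.040171173
574,0.037160555
575,0.034355034
576,0.031742938
577,0.02931301
578,0.027054418
579,0.024956758
580,0.023010068
581,0.021206904
582,0.019539179
583,0.017996891
584,0.01657078
585,0.015252269
586,0.014033417
587,0.012906868
588,0.011865813
589,0.01090394
590,0.010015408
591,0.0091956842
592,0.0084407319
593,0.0077459616
594,0.0071070249
595,0.0065198153
596,0.0059804659
597,0.005485345
598,0.0050310499
599,0.0046144002
600,0.004232429
601,0.0038821535
602,0.003560838
603,0.0032661736
604,0.0029960191
605,0.0027483914
606,0.0025214563
607,0.0023135189
608,0.0021230149
609,0.0019485018000000001
610,0.0017886506
611,0.0016422208
612,0.0015080552
613,0.0013851039
614,0.0012724082
615,0.0011690926
616,0.0010743578
617,9.8747387e-4
618,9.0777412e-4
619,8.3464971e-4
620,7.675445e-4
621,7.0596799e-4
622,6.4946792e-4
623,5.9761278e-4
624,5.5000884e-4
625,5.062967e-4
626,4.6614828e-4
627,4.2926401e-4
628,3.9537027e-4
629,3.6421712e-4
630,3.3557615e-4
631,3.0923748e-4
632,2.850133e-4
633,2.6273398e-4
634,2.422432e-4
635,2.2339691e-4
636,2.060625e-4
637,1.9011785e-4
638,1.754506e-4
639,1.6195736e-4
640,1.4954302e-4
641,1.3811727e-4
642,1.2759658e-4
643,1.1790688e-4
644,1.0898037e-4
645,1.0075491e-4
646,9.3173594e-5
647,8.6184248e-5
648,7.9739068e-5
649,7.3794223e-5
650,6.8309521e-5
651,6.3138304e-5
652,5.8371738e-5
653,5.3977191e-5
654,4.9924733e-5
655,4.6186908e-5
656,4.2738526e-5
657,3.955647e-5
658,3.6619523e-5
659,3.3908204e-5
660,3.1404628e-5
661,2.9092367e-5
662,2.6956329e-5
663,2.4982651e-5
664,2.3158589e-5
665,2.1472432e-5
666,1.9913413e-5
667,1.8471628e-5
668,1.7137971e-5
669,1.5904064e-5
670,1.4762197e-5
671,1.3705276e-5
672,1.2726769e-5
673,1.1820662e-5
674,1.0981419e-5
675,1.0203938e-5
676,9.4835185e-6
677,8.8158307e-6
678,8.1968826e-6
679,7.6229944e-6
680,7.0907728e-6
681,6.5970883e-6
682,6.1390541e-6
683,5.7140064e-6
684,5.3194872e-6
685,4.9532272e-6
686,4.6131316e-6
687,4.2972657e-6
688,4.0038428e-6
689,3.7312121e-6
690,3.4778482e-6
691,3.2423415e-6
692,3.0233886e-6
693,2.8197848e-6
694,2.6304157e-6
695,2.4542506e-6
696,2.2903358e-6
697,2.1377891e-6
698,1.9957936e-6
699,1.8635934e-6
700,1.7404883e-6
701,1.62583e-6
702,1.519018e-6
703,1.4194958e-6
704,1.3267478e-6
705,1.2402962e-6
706,1.1596979e-6
707,1.0845421e-6
708,1.0144479e-6
709,9.4906187e-7
710,8.880561e-7
711,8.3112638e-7
712,7.7799033e-7
713,7.283858e-7
714,6.8206939e-7
715,6.3881507e-7
716,5.9841286e-7
717,5.6066771e-7
718,5.2539836e-7
719,4.9243636e-7
720,4.616251e-7
721,4.32819e-7
722,4.0588267e-7
723,3.8069018e-7
724,3.5712438e-7
725,3.3507628e-7
726,3.1444444e-7
727,2.9513445e-7
728,2.7705839e-7
729,2.6013445e-7
730,2.4428638e-7
731,2.2944318e-7
732,2.1553873e-7
733,2.0251136e-7
734,1.9030365e-7
735,1.7886205e-7
736,1.6813662e-7
737,1.5808082e-7
738,1.4865124e-7
739,1.3980737e-7
740,1.3151142e-7
741,1.2372814e-7
742,1.1642462e-7
743,1.0957014e-7
744,1.0313601e-7
745,9.7095456e-8
746,9.1423467e-8
747,8.6096674e-8
748,8.1093248e-8
749,7.6392791e-8
750,7.1976237e-8
751,6.7825766e-8
752,6.3924718e-8
753,6.0257512e-8
754,5.6809579e-8
755,5.356729e-8
756,5.0517895e-8
757,4.7649463e-8
758,4.4950829e-8
759,4.2411544e-8
760,4.0021823e-8
761,3.7772506e-8
762,3.5655015e-8
763,3.3661315e-8
764,3.178388e-8
765,3.0015658e-8
766,2.8350042e-8
767,2.6780837e-8
768,2.5302239e-8
769,2.3908806e-8
770,2.2595433e-8
771,2.1357337e-8
772,2.0190026e-8
773,1.9089291e-8
774,1.805118e-8
775,1.7071986e-8
776,1.6148229e-8
777,1.5276642e-8
778,1.4454159e-8
779,1.3677901e-8
780,1.2945163e-8
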