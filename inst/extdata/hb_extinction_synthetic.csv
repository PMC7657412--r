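# Synthetic whole-blood absorption table (150 g/L hemoglobin), mm^-1.
# Smooth reconstruction of standard HbO2/HbR visible-band spectra; not
# a verbatim copy of any published compilation.
# reference_hb_concentration_g_per_l: 150
wavelength_nm,mua_hbo_mm1,mua_hbr_mm1
450,33.63702,36.412974
451,32.488037,35.44819
452,31.366674,34.507543
453,30.277602,33.591064
454,29.224795,32.698734
455,28.211584,31.830483
456,27.240712,30.9862
457,26.314397,30.165736
458,25.43439,29.368902
459,24.602045,28.595478
460,23.818369,27.845215
461,23.075452,27.116764
462,22.36466,26.408638
463,21.685644,25.720359
464,21.037992,25.051457
465,20.421246,24.401468
466,19.834909,23.769932
467,19.278456,23.156398
468,18.751343,22.560422
469,18.253015,21.981565
470,17.782918,21.419396
471,17.336228,20.870278
472,16.909015,20.332157
473,16.501983,19.806832
474,16.115731,19.295898
475,15.750777,18.800763
476,15.407565,18.322662
477,15.086484,17.86267
478,14.787885,17.421717
479,14.512095,17.000608
480,14.259428,16.600032
481,14.033857,16.215913
482,13.835586,15.844267
483,13.659568,15.485781
484,13.501083,15.141056
485,13.355675,14.810622
486,13.219102,14.494939
487,13.087308,14.194412
488,12.956398,13.909396
489,12.822631,13.640205
490,12.682424,13.387123
491,12.536366,13.144908
492,12.388631,12.909681
493,12.241077,12.683621
494,12.095475,12.468747
495,11.953514,12.266942
496,11.816805,12.079969
497,11.686882,11.909497
498,11.565217,11.757127
499,11.453225,11.624419
500,11.35228,11.512925
501,11.251075,11.420919
502,11.141904,11.345095
503,11.031343,11.284706
504,10.92572,11.23908
505,10.831124,11.207609
506,10.753452,11.189746
507,10.698485,11.184998
508,10.671999,11.192917
509,10.679908,11.2131
510,10.72844,11.245183
511,10.809724,11.291921
512,10.913281,11.355431
513,11.041952,11.434445
514,11.19885,11.52772
515,11.387417,11.634021
516,11.611501,11.752102
517,11.87545,11.880692
518,12.184215,12.018481
519,12.543478,12.164108
520,12.959806,12.316153
521,13.467778,12.461705
522,14.091316,12.594904
523,14.821049,12.725188
524,15.645584,12.862415
525,16.55022,13.016876
526,17.515743,13.199391
527,18.517393,13.421496
528,19.52411,13.695717
529,20.498237,14.035972
530,21.395835,14.458092
531,22.244111,15.003012
532,23.095812,15.690775
533,23.940213,16.506798
534,24.765303,17.433628
535,25.557853,18.449019
536,26.303553,19.524205
537,26.987213,20.622534
538,27.593033,21.698681
539,28.104956,22.698715
540,28.507074,23.561336
541,28.754635,24.282904
542,28.810914,24.907577
543,28.675328,25.443775
544,28.351117,25.902393
545,27.845215,26.296354
546,27.084342,26.640206
547,26.089625,26.949769
548,25.003235,27.241875
549,23.949715,27.534202
550,23.034419,27.845215
551,22.23538,28.145335
552,21.476866,28.391642
553,20.769685,28.583465
554,20.12311,28.720472
555,19.545199,28.802662
556,18.991119,28.838093
557,18.452029,28.826059
558,17.984246,28.753857
559,17.638691,28.609238
560,17.463769,28.3807
561,17.46148,28.092698
562,17.594674,27.775892
563,17.85573,27.428978
564,18.239347,27.050866
565,18.741972,26.640693
566,19.453979,26.197844
567,20.406227,25.721963
568,21.496061,25.212975
569,22.5984,24.67109
570,23.561336,24.096821
571,24.4396,23.468432
572,25.362912,22.778842
573,26.266444,22.049676
574,27.076145,21.300778
575,27.710352,20.549968
576,28.083626,19.812941
577,28.112958,19.085102
578,27.911275,18.356296
579,27.555572,17.631857
580,26.922841,16.916512
581,25.908314,16.214396
582,24.439332,15.529062
583,22.490366,14.844901
584,20.076722,14.156899
585,17.433399,13.481933
586,14.842165,12.834055
587,12.487377,12.224688
588,10.464945,11.662948
589,8.804959,11.156038
590,7.496789,10.709698
591,6.422862,10.324493
592,5.483894,9.988598
593,4.674881,9.689722
594,3.986456,9.417069
595,3.406844,9.161033
596,2.923347,8.913003
597,2.523393,8.665253
598,2.19523,8.410903
599,1.928322,8.143945
600,1.713552,7.859312
601,1.540959,7.558073
602,1.399926,7.248644
603,1.283162,6.937179
604,1.185122,6.629039
605,1.101519,6.328796
606,1.02899,6.040259
607,0.964856,5.766538
608,0.906963,5.510122
609,0.85356,5.272964
610,0.803227,5.056584
611,0.757473,4.855303
612,0.717684,4.663002
613,0.682659,4.480172
614,0.651398,4.307182
615,0.623057,4.144297
616,0.59692,3.991693
617,0.572371,3.849477
618,0.548883,3.717699
619,0.526005,3.59637
620,0.503356,3.485471
621,0.481143,3.384808
622,0.459844,3.293266
623,0.439516,3.209554
624,0.420204,3.132508
625,0.401937,3.061078
626,0.384735,2.994304
627,0.368607,2.931308
628,0.353553,2.871282
629,0.33957,2.81348
630,0.326646,2.757212
631,0.314579,2.703438
632,0.303177,2.653209
633,0.292442,2.606034
634,0.282372,2.56146
635,0.272963,2.519063
636,0.26421,2.478447
637,0.256106,2.439241
638,0.248643,2.401094
639,0.241815,2.363677
640,0.235613,2.326682
641,0.230132,2.290579
642,0.225365,2.255899
643,0.221171,2.222445
644,0.217421,2.190029
645,0.213998,2.158474
646,0.210791,2.127613
647,0.207695,2.097288
648,0.204613,2.067349
649,0.201453,2.037654
650,0.198129,2.008068
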