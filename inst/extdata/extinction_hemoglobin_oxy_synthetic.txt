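# synthetic oxyhemoglobin effective extinction: spline through published-style molar extinction anchors, scaled to whole blood (150 g/L), units 1/mm per unit blood volume fraction
# columns: wavelength_nm  value
450 33.637
455 28.1944
460 23.8269
465 20.4347
470 17.7829
475 15.7148
480 14.2594
485 13.3732
490 12.6824
495 11.911
500 11.2088
505 10.7707
510 10.7284
515 11.2805
520 12.9598
525 16.4982
530 21.3958
535 25.8243
540 28.5071
545 28.5436
550 24.8444
555 19.2775
560 16.0645
565 19.0643
570 24.4356
575 26.7554
580 24.6221
585 14.749
590 6.42582
595 3.05887
600 1.71355
605 1.1116
610 0.80644
615 0.628541
620 0.504427
625 0.403787
630 0.326646
635 0.272687
640 0.236684
645 0.213586
650 0.197058
655 0.182839
660 0.17082
665 0.161472
670 0.154643
675 0.150124
680 0.147794
685 0.147539
690 0.148978
695 0.151698
700 0.155291
705 0.159466
710 0.164478
715 0.170767
720 0.178852
725 0.189247
730 0.202072
735 0.217339
740 0.235037
745 0.255101
750 0.277381
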