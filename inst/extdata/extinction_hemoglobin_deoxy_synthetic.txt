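# synthetic deoxyhemoglobin effective extinction: spline through published-style molar extinction anchors, scaled to whole blood (150 g/L), units 1/mm per unit blood volume fraction
# columns: wavelength_nm  value
450 29.7408
455 27.525
460 25.7033
465 24.2553
470 22.4904
475 20.037
480 17.671
485 15.9219
490 14.4581
495 13.0827
500 12.3162
505 12.5429
510 13.3871
515 14.3867
520 15.5291
525 16.9411
530 18.742
535 21.0146
540 23.5613
545 25.9942
550 27.8452
555 28.6013
560 27.8452
565 25.5623
570 22.4904
575 19.2829
580 16.0645
585 13.0282
590 10.7097
595 9.19799
600 7.85931
605 6.36649
610 5.05658
615 4.12137
620 3.48601
625 3.05985
630 2.75721
635 2.52074
640 2.32668
645 2.16045
650 2.00807
655 1.86167
660 1.72801
665 1.61239
670 1.50926
675 1.41205
680 1.31569
685 1.21801
690 1.12343
695 1.03658
700 0.96066
705 0.897412
710 0.846308
715 0.806533
720 0.777524
725 0.758614
730 0.747931
735 0.743582
740 0.743902
745 0.747337
750 0.752356
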