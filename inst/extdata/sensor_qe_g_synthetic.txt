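# synthetic idealized green-channel quantum efficiency (Gaussian, relative units)
# columns: wavelength_nm  value
450 0.135335
455 0.167973
460 0.205924
465 0.249352
470 0.298234
475 0.352322
480 0.411112
485 0.473827
490 0.539408
495 0.606531
500 0.673638
505 0.738991
510 0.800737
515 0.856997
520 0.905955
525 0.945959
530 0.975611
535 0.993846
540 1
545 0.993846
550 0.975611
555 0.945959
560 0.905955
565 0.856997
570 0.800737
575 0.738991
580 0.673638
585 0.606531
590 0.539408
595 0.473827
600 0.411112
605 0.352322
610 0.298234
615 0.249352
620 0.205924
625 0.167973
630 0.135335
635 0.107701
640 0.084658
645 0.0657285
650 0.0504055
655 0.0381804
660 0.0285655
665 0.0211097
670 0.0154084
675 0.011109
680 0.00791096
685 0.00556445
690 0.00386592
695 0.00265291
700 0.00179817
705 0.00120386
710 0.000796087
715 0.000519976
720 0.000335463
725 0.000213768
730 0.000134549
735 8.36483e-05
740 5.13655e-05
745 3.11548e-05
750 1.86645e-05
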