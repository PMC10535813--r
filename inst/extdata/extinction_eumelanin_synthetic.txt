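# synthetic eumelanin effective extinction: power-law approximation to melanosome interior absorption, units 1/mm per unit melanin volume fraction
# columns: wavelength_nm  value
450 99.2715
455 95.5266
460 91.9617
465 88.5662
470 85.3303
475 82.2451
480 79.3021
485 76.4932
490 73.8111
495 71.2489
500 68.8
505 66.4584
510 64.2185
515 62.0747
520 60.0223
525 58.0563
530 56.1725
535 54.3667
540 52.6349
545 50.9735
550 49.379
555 47.8481
560 46.3778
565 44.9651
570 43.6073
575 42.3019
580 41.0464
585 39.8384
590 38.6758
595 37.5565
600 36.4786
605 35.4401
610 34.4395
615 33.4749
620 32.5448
625 31.6477
630 30.7821
635 29.9469
640 29.1405
645 28.362
650 27.6099
655 26.8834
660 26.1813
665 25.5026
670 24.8464
675 24.2118
680 23.5979
685 23.0039
690 22.429
695 21.8724
700 21.3335
705 20.8116
710 20.306
715 19.8161
720 19.3414
725 18.8811
730 18.4349
735 18.0021
740 17.5824
745 17.1751
750 16.78
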