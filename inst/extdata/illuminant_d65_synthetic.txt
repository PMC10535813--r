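# synthetic approximation of the CIE D65 relative spectral power distribution (spline through 10-nm anchors, 100 at 560 nm)
# columns: wavelength_nm  value
450 117.01
455 117.969
460 117.81
465 116.064
470 114.86
475 115.817
480 115.92
485 112.486
490 108.81
495 108.362
500 109.35
505 109.239
510 107.8
515 105.687
520 104.79
525 106.339
530 107.69
535 106.363
540 104.41
545 104.103
550 104.05
555 102.511
560 100
565 97.5903
570 96.33
575 96.5566
580 95.79
585 92.1146
590 88.69
595 88.6574
600 90.01
605 90.1922
610 89.6
615 89.0015
620 87.7
625 85.202
630 83.29
635 83.4492
640 83.7
645 82.0636
650 80.03
655 79.4577
660 80.21
665 81.5432
670 82.28
675 81.3171
680 78.28
685 73.5395
690 69.72
695 69.261
700 71.61
705 74.819
710 74.35
715 67.513
720 61.6
725 63.6727
730 69.89
735 74.5098
740 75.09
745 70.7542
750 63.59
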