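# synthetic idealized red-channel quantum efficiency (Gaussian, relative units)
# columns: wavelength_nm  value
450 0.00161835
455 0.00238762
460 0.00347933
465 0.005008
470 0.00711986
475 0.0099981
480 0.0138676
485 0.0189987
490 0.025709
495 0.0343624
500 0.045365
505 0.0591557
510 0.0761922
515 0.096931
520 0.121802
525 0.151176
530 0.185332
535 0.224417
540 0.268411
545 0.31709
550 0.370001
555 0.426444
560 0.485467
565 0.545878
570 0.606275
575 0.665092
580 0.720664
585 0.771297
590 0.81536
595 0.851364
600 0.87805
605 0.894462
610 0.9
615 0.894462
620 0.87805
625 0.851364
630 0.81536
635 0.771297
640 0.720664
645 0.665092
650 0.606275
655 0.545878
660 0.485467
665 0.426444
670 0.370001
675 0.31709
680 0.268411
685 0.224417
690 0.185332
695 0.151176
700 0.121802
705 0.096931
710 0.0761922
715 0.0591557
720 0.045365
725 0.0343624
730 0.025709
735 0.0189987
740 0.0138676
745 0.0099981
750 0.00711986
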