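# synthetic idealized blue-channel quantum efficiency (Gaussian, relative units)
# columns: wavelength_nm  value
450 0.729803
455 0.768004
460 0.791878
465 0.8
470 0.791878
475 0.768004
480 0.729803
485 0.679493
490 0.61987
495 0.554055
500 0.485225
505 0.41636
510 0.350052
515 0.288358
520 0.232739
525 0.184053
530 0.142611
535 0.108268
540 0.0805351
545 0.0586957
550 0.0419145
555 0.0293264
560 0.0201044
565 0.0135039
570 0.0088872
575 0.00573069
580 0.00362065
585 0.00224131
590 0.00135942
595 0.000807875
600 0.000470404
605 0.00026837
610 0.000150015
615 8.21621e-05
620 4.40905e-05
625 2.31823e-05
630 1.19427e-05
635 6.0282e-06
640 2.98132e-06
645 1.44466e-06
650 6.85902e-07
655 3.19076e-07
660 1.45433e-07
665 6.49483e-08
670 2.84191e-08
675 1.2184e-08
680 5.11806e-09
685 2.10648e-09
690 8.4947e-10
695 3.35641e-10
700 1.29938e-10
705 4.92876e-11
710 1.83179e-11
715 6.67036e-12
720 2.37991e-12
725 8.3197e-13
730 2.84965e-13
735 9.56342e-14
740 3.14464e-14
745 1.01313e-14
750 3.19815e-15
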